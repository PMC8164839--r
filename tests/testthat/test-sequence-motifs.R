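test_that("read_fasta parses, normalises case and strips gaps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">h human", "RARGQG", ">m mouse", "rarg-qg"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("h", "m"))
  expect_equal(rec$species, c("human", "mouse"))
  expect_equal(rec$sequence, c("RARGQG", "RARGQG"))
})

test_that("read_fasta rejects empty files and illegal residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_error(read_fasta(f), "no sequences")
  writeLines(c(">h", "RAR7QG"), f)
  expect_error(read_fasta(f), "illegal residue '7' in record h at offset 4")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("scan_tbm finds the published vinculin motif patterns", {
  hit <- scan_tbm("RARGQG")
  expect_equal(hit$motif_class, "canonical")
  expect_equal(c(hit$start, hit$end), c(1L, 6L))
  hit <- scan_tbm("RRQGKG")
  expect_equal(hit$motif_class, "canonical")
  expect_equal(c(hit$start, hit$end), c(1L, 6L))
  hit <- scan_tbm("RGLVAEG")
  expect_equal(hit$motif_class, "non_canonical")
  expect_equal(c(hit$start, hit$end), c(1L, 7L))
  expect_equal(nrow(scan_tbm("KARGQG")), 0L)
})

test_that("class selection, overlap reporting and anchor rules hold", {
  # a heptamer window whose first 6 residues are also a canonical hexamer
  seq <- "RAAGAGG"   # canonical R-A-A-G-A-G at 1-6; nc R-A-A-G-A-G-G at 1-7
  both <- scan_tbm(seq)
  expect_equal(nrow(both), 2L)
  expect_setequal(both$motif_class, c("canonical", "non_canonical"))
  only_c <- scan_tbm(seq, classes = "canonical")
  expect_equal(only_c$motif_class, "canonical")
  # X matches unconstrained positions but never an anchor
  expect_equal(nrow(scan_tbm("RXXGXG")), 1L)
  expect_equal(nrow(scan_tbm("XARGQG")), 0L)  # R anchor lost
  expect_equal(nrow(scan_tbm("RARXQG")), 0L)  # O anchor cannot be X
  expect_equal(nrow(scan_tbm("RARGQX")), 0L)  # G anchor lost
})

test_that("scan_tbm equals the brute-force window oracle on random sequences", {
  set.seed(42)
  lens <- c(10, 6, 7, sample(10:2000, 997, replace = TRUE))
  for (len in lens) {
    seq <- random_protein(len)
    got <- scan_tbm(seq)
    want <- brute_force_tbm(seq)
    expect_equal(got[c("motif_class", "start", "end", "matched")], want,
                 ignore_attr = TRUE)
  }
})

test_that("every hit satisfies its length and anchor invariants", {
  set.seed(7)
  for (i in 1:50) {
    seq <- random_protein(500)
    hits <- scan_tbm(seq)
    if (!nrow(hits)) next
    len <- hits$end - hits$start + 1L
    expect_true(all(len[hits$motif_class == "canonical"] == 6L))
    expect_true(all(len[hits$motif_class == "non_canonical"] == 7L))
    expect_equal(hits$matched, substring(seq, hits$start, hits$end))
    expect_true(all(substring(hits$matched, 1, 1) == "R"))
    expect_true(all(substring(hits$matched, len, len) == "G"))
  }
})

test_that("prepending k residues shifts every hit start by k", {
  set.seed(11)
  seq <- random_protein(300)
  base <- scan_tbm(seq)
  for (k in c(1, 5, 40)) {
    prefix <- paste(rep("D", k), collapse = "")  # D can't anchor or O-match
    shifted <- scan_tbm(paste0(prefix, seq))
    expect_equal(shifted$start, base$start + k)
    expect_equal(shifted$matched, base$matched)
  }
})

test_that("sequences lacking R or lacking G yield no hits", {
  set.seed(13)
  no_r <- paste(sample(strsplit("ACDEFGHIKLMNPQSTVWY", "")[[1]], 500,
                       replace = TRUE), collapse = "")
  no_g <- paste(sample(strsplit("ACDEFHIKLMNPQRSTVWY", "")[[1]], 500,
                       replace = TRUE), collapse = "")
  expect_equal(nrow(scan_tbm(no_r)), 0L)
  expect_equal(nrow(scan_tbm(no_g)), 0L)
})

test_that("read_alignment builds correct residue/column maps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_aln_fasta(list(a = "R-G", b = "RAG"), f)
  aln <- read_alignment(f)
  expect_equal(aln$ncol, 3L)
  expect_equal(aln$maps[["a"]]$res_to_col, c(1L, 3L))
  expect_equal(aln$maps[["a"]]$col_to_res, c(1L, NA, 2L))
  expect_equal(aln$maps[["b"]]$res_to_col, 1:3)
  # identical ungapped rows give identity maps
  write_aln_fasta(list(a = "RAG", b = "RAG"), f)
  aln <- read_alignment(f)
  expect_equal(aln$maps[["a"]]$res_to_col, 1:3)
})

test_that("column maps round-trip on random gapped alignments", {
  set.seed(3)
  for (i in 1:20) {
    n_col <- sample(20:60, 1)
    rows <- lapply(1:3, function(j) {
      ch <- sample(c("A", "R", "G", "-"), n_col, replace = TRUE,
                   prob = c(0.4, 0.2, 0.2, 0.2))
      if (all(ch == "-")) ch[1] <- "A"
      paste(ch, collapse = "")
    })
    names(rows) <- paste0("s", 1:3)
    f <- withr::local_tempfile(fileext = ".fasta")
    write_aln_fasta(rows, f)
    aln <- read_alignment(f)
    for (id in names(rows)) {
      m <- aln$maps[[id]]
      nongap <- which(!is.na(m$col_to_res))
      expect_equal(m$res_to_col[m$col_to_res[nongap]], nongap)
    }
  }
})

test_that("read_alignment reads Clustal and rejects ragged rows", {
  f <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (2.0) multiple sequence alignment", "", "",
               "a   RARGQG", "b   RARGQG"), f)
  aln <- read_alignment(f)
  expect_equal(nrow(aln$records), 2L)
  expect_equal(aln$records$sequence, c("RARGQG", "RARGQG"))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "RAG", ">b", "RAGG"), f2)
  expect_error(read_alignment(f2))
})

test_that("conservation_report classifies conserved/degenerate/absent", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_aln_fasta(list(human = "AARARGQGAA",
                       mouse = "AARARGQGAA",    # identical -> conserved
                       fly   = "AARARFQGAA",    # O position violated
                       worm  = "AAKARGQGAA"),   # R anchor lost
                  f)
  tab <- conservation_report(read_alignment(f), "human")
  expect_s3_class(tab, "conservation_table")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$start, 3L)
  expect_equal(tab$human, "conserved")
  expect_equal(tab$mouse, "conserved")
  expect_equal(tab$fly, "degenerate")
  expect_equal(tab$worm, "absent")
})

test_that("conservation windows are contiguous and survive reference gaps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  # reference motif interrupted by an alignment gap column
  write_aln_fasta(list(ref   = "RAR-GQG",
                       other = "RARAGQG"), f)
  aln <- read_alignment(f)
  tab <- conservation_report(aln, "ref")
  expect_equal(nrow(tab), 1L)
  expect_equal(c(tab$col_start, tab$col_end), c(1L, 7L))
  # 'other' has an extra residue under the window -> not the same hexamer
  expect_equal(tab$other, "absent")
  expect_equal(tab$ref, "conserved")
})

test_that("a reference without motifs yields an empty table with a warning", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_aln_fasta(list(a = "AAAAAAAA", b = "AAAAAAAA"), f)
  aln <- read_alignment(f)
  expect_warning(tab <- conservation_report(aln, "a"), "no motif hits")
  expect_equal(nrow(tab), 0L)
  expect_error(conservation_report(aln, "zz"), "not in alignment")
})

test_that("the synthetic vinculin surrogate carries exactly the published loci", {
  rec <- synthetic_vcl_record()
  expect_equal(nchar(rec$sequence), 1066L)
  hits <- scan_tbm(rec)
  expect_equal(hits$start, c(339L, 449L, 520L))
  expect_equal(hits$motif_class,
               c("canonical", "canonical", "non_canonical"))
  expect_equal(hits$matched, c("RARGQG", "RRQGKG", "RGLVAEG"))
  # deterministic
  expect_identical(rec, synthetic_vcl_record())
})
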