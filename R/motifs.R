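#' Read protein sequences from FASTA
#'
#' Reads one record per FASTA entry (order preserved), upper-cases the
#' sequences and strips alignment gaps; characters outside the 20
#' one-letter amino-acid codes plus X (unknown) are rejected with the
#' offending record and offset. The species label is taken from the
#' second whitespace-separated token of the header when present,
#' otherwise it repeats the id.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `species`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no sequences in ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  species <- vapply(strsplit(headers, "\\s+"), function(t)
    if (length(t) >= 2) t[2] else t[1], "")
  seqs <- toupper(gsub("-", "", as.character(set)))
  for (i in seq_along(seqs)) validate_protein(seqs[i], ids[i])
  data.frame(id = ids, species = species, sequence = seqs,
             stringsAsFactors = FALSE, row.names = NULL)
}

protein_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

validate_protein <- function(seq, id) {
  if (!nzchar(seq)) stop("empty sequence for record ", id)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% protein_alphabet)
  if (length(bad))
    stop(sprintf("illegal residue '%s' in record %s at offset %d",
                 chars[bad[1]], id, bad[1]))
  invisible(TRUE)
}

# Tankyrase-binding-motif patterns. Anchors are literal (R, G) or the
# O-class {G,P,A,C}; unconstrained positions accept any residue including
# X, but X never satisfies an anchor.
tbm_patterns <- list(
  canonical     = list(regex = "R..[GPAC].G", len = 6L),
  non_canonical = list(regex = "R...[GPAC].G", len = 7L)
)

#' Scan a protein sequence for tankyrase-binding motifs
#'
#' Finds every window matching the canonical hexamer `R-X-X-O-X-G` and/or
#' the non-canonical heptamer `R-X-X-X-O-X-G`, with O one of G, P, A, C
#' and X any residue. All overlapping and nested hits are reported;
#' coordinates are 1-based inclusive.
#'
#' @param record one-row data.frame with `id` and `sequence` (as from
#'   [read_fasta()]), or a plain sequence string.
#' @param classes subset of `c("canonical", "non_canonical")`.
#' @return data.frame of hits: `record_id`, `motif_class`, `start`,
#'   `end`, `matched`, sorted by start then class. Zero rows if none.
#' @export
scan_tbm <- function(record, classes = c("canonical", "non_canonical")) {
  classes <- match.arg(classes, names(tbm_patterns), several.ok = TRUE)
  if (is.character(record) && length(record) == 1)
    record <- data.frame(id = "seq", sequence = toupper(record),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(record), nrow(record) == 1)
  validate_protein(record$sequence, record$id)
  seq <- record$sequence
  hits <- lapply(classes, function(cl) {
    pat <- tbm_patterns[[cl]]
    # lookahead so overlapping matches are all found
    m <- gregexpr(paste0("(?=", pat$regex, ")"), seq, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    if (!length(starts) || m[1] == -1) return(NULL)
    data.frame(record_id = record$id, motif_class = cl,
               start = starts, end = starts + pat$len - 1L,
               matched = substring(seq, starts, starts + pat$len - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(record_id = character(), motif_class = character(),
                      start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  out <- out[order(out$start, out$motif_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan every record of a FASTA table
#'
#' @param records data.frame from [read_fasta()].
#' @inheritParams scan_tbm
#' @return data.frame of hits across all records.
#' @export
scan_tbm_all <- function(records, classes = c("canonical", "non_canonical")) {
  do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    scan_tbm(records[i, , drop = FALSE], classes)))
}

#' Read a precomputed protein multiple alignment
#'
#' Accepts aligned FASTA or Clustal (`.aln`) files; the alignment itself
#' is always computed externally (e.g. ClustalX) and only read here. For
#' each record a bidirectional map between ungapped residue positions and
#' alignment columns is built.
#'
#' @param path alignment file.
#' @param format `"auto"` (sniff Clustal header), `"fasta"` or
#'   `"clustal"`.
#' @return object of class `protein_alignment`: list with `records`
#'   (data.frame id/species/sequence, ungapped), `aligned` (character
#'   vector of gapped rows, named by id), `ncol`, and `maps` — per record
#'   a list with `res_to_col` (integer vector over residues) and
#'   `col_to_res` (integer vector over columns, NA at gaps).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  rows <- as.character(aln)
  if (length(unique(nchar(rows))) != 1)
    stop("ragged alignment: rows differ in length")
  ids <- vapply(strsplit(names(rows), "\\s+"), `[`, "", 1)
  names(rows) <- ids
  ungapped <- toupper(gsub("-", "", rows))
  maps <- lapply(rows, function(r) {
    gap <- strsplit(r, "")[[1]] == "-"
    res_to_col <- which(!gap)
    col_to_res <- rep(NA_integer_, length(gap))
    col_to_res[!gap] <- seq_along(res_to_col)
    list(res_to_col = res_to_col, col_to_res = col_to_res)
  })
  for (i in seq_along(ids)) validate_protein(ungapped[i], ids[i])
  structure(list(
    records = data.frame(id = ids, species = ids, sequence = unname(ungapped),
                         stringsAsFactors = FALSE),
    aligned = toupper(rows), ncol = unique(nchar(rows)), maps = maps),
    class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment: %d sequences x %d columns>\n",
              nrow(x$records), x$ncol))
  invisible(x)
}

#' Motif conservation across an alignment
#'
#' Scans the reference sequence for tankyrase-binding motifs, projects
#' each motif locus onto its alignment-column window and classifies every
#' other species at that window:
#' \describe{
#'   \item{conserved}{the ungapped residues under the window themselves
#'     match the same motif-class pattern;}
#'   \item{degenerate}{the R...G frame is intact (same motif length,
#'     anchor R and G present) but the O-position constraint fails;}
#'   \item{absent}{anything else, including indel-shifted windows.}
#' }
#'
#' @param alignment a [read_alignment()] object.
#' @param reference_id row id of the reference sequence.
#' @param classes motif classes to scan.
#' @return data.frame of class `conservation_table`: one row per
#'   reference motif locus with its coordinates, alignment-column window,
#'   and one classification column per species. Zero rows (with a
#'   warning) if the reference has no motifs.
#' @export
conservation_report <- function(alignment, reference_id,
                                classes = c("canonical", "non_canonical")) {
  stopifnot(inherits(alignment, "protein_alignment"))
  ids <- alignment$records$id
  if (!reference_id %in% ids)
    stop("reference '", reference_id, "' not in alignment")
  ref <- alignment$records[ids == reference_id, , drop = FALSE]
  hits <- scan_tbm(ref, classes)
  others <- setdiff(ids, reference_id)
  base <- data.frame(record_id = character(), motif_class = character(),
                     start = integer(), end = integer(),
                     matched = character(), col_start = integer(),
                     col_end = integer(), stringsAsFactors = FALSE)
  for (sp in ids) base[[sp]] <- character()
  if (!nrow(hits)) {
    warning("reference '", reference_id, "' has no motif hits")
    return(structure(base, class = c("conservation_table", "data.frame")))
  }
  map <- alignment$maps[[which(ids == reference_id)]]
  out <- hits
  out$col_start <- map$res_to_col[hits$start]
  out$col_end <- map$res_to_col[hits$end]
  out[[reference_id]] <- "conserved"
  for (sp in others) {
    cls <- character(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      win <- substring(alignment$aligned[[sp]],
                       out$col_start[i], out$col_end[i])
      cand <- gsub("-", "", win)
      pat <- tbm_patterns[[hits$motif_class[i]]]
      if (grepl(paste0("^", pat$regex, "$"), cand)) {
        cls[i] <- "conserved"
      } else if (nchar(cand) == pat$len &&
                 substring(cand, 1, 1) == "R" &&
                 substring(cand, pat$len, pat$len) == "G") {
        cls[i] <- "degenerate"
      } else {
        cls[i] <- "absent"
      }
    }
    out[[sp]] <- cls
  }
  rownames(out) <- NULL
  structure(out, class = c("conservation_table", "data.frame"))
}
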