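# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: the motif oracle checks windows character by
# character (no regex), the Mann-Whitney oracle enumerates group
# assignments, the Kruskal-Wallis oracle is the textbook rank formula.

O_CLASS <- c("G", "P", "A", "C")

# sliding-window motif checker: every window tested on raw characters
brute_force_tbm <- function(seq, classes = c("canonical", "non_canonical")) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- list()
  if ("canonical" %in% classes && n >= 6) {
    s <- seq_len(n - 5)
    hit <- ch[s] == "R" & ch[s + 3] %in% O_CLASS & ch[s + 5] == "G"
    if (any(hit))
      out$canonical <- data.frame(
        motif_class = "canonical", start = s[hit], end = s[hit] + 5L,
        matched = substring(seq, s[hit], s[hit] + 5L),
        stringsAsFactors = FALSE)
  }
  if ("non_canonical" %in% classes && n >= 7) {
    s <- seq_len(n - 6)
    hit <- ch[s] == "R" & ch[s + 4] %in% O_CLASS & ch[s + 6] == "G"
    if (any(hit))
      out$non_canonical <- data.frame(
        motif_class = "non_canonical", start = s[hit], end = s[hit] + 6L,
        matched = substring(seq, s[hit], s[hit] + 6L),
        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(motif_class = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  res <- res[order(res$start, res$motif_class), , drop = FALSE]
  rownames(res) <- NULL
  res
}

random_protein <- function(len) {
  paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"),
               len, replace = TRUE), collapse = "")
}

# full-enumeration two-sided Mann-Whitney p-value (no ties assumed)
permutation_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, u_of)
  # two-sided: distance of U from its mean
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# textbook tie-corrected Kruskal-Wallis H
kw_formula_H <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- rank(v)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) -
    3 * (N + 1)
  tie <- table(v)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# regular n-gon approximation of a circle
circle_contour <- function(r = 100, n = 4096) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour(r * cos(th), r * sin(th), label = "circle", validate = FALSE)
}

# minimal aligned-FASTA writer for alignment fixtures
write_aln_fasta <- function(rows, path) {
  writeLines(unlist(lapply(names(rows), function(id)
    c(paste0(">", id), rows[[id]]))), path)
  path
}
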