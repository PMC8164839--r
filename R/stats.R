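#' Mann-Whitney comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the medians of two
#' CShin populations. The exact enumeration p-value is used when
#' `n_a * n_b <= 400` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. The reported U is
#' `min(U_a, U_b)`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list of class `shape_test`: `method`, `statistic` (U),
#'   `p_value`, `pairwise` (NULL here).
#' @export
mann_whitney <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    warning("all values identical across both groups; p = 1")
    return(structure(list(method = "Mann-Whitney U",
                          statistic = length(a) * length(b) / 2,
                          p_value = 1, pairwise = NULL),
                     class = "shape_test"))
  }
  ties <- any(duplicated(pooled))
  exact <- (length(a) * length(b) <= 400) && !ties
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  u_a <- unname(wt$statistic)
  u <- min(u_a, length(a) * length(b) - u_a)
  structure(list(method = "Mann-Whitney U", statistic = u,
                 p_value = unname(wt$p.value), pairwise = NULL),
            class = "shape_test")
}

#' @export
print.shape_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise)
  }
  invisible(x)
}

check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            !is.null(names(groups)), all(nzchar(names(groups))))
  bad <- names(groups)[vapply(groups, length, 1L) < 2]
  if (length(bad))
    stop("groups with <2 observations: ", paste(bad, collapse = ", "))
  invisible(groups)
}

#' Kruskal-Wallis test over named groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k-1 degrees of
#' freedom.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations).
#' @return `shape_test` with `statistic` = H.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(values)) == 1)
    return(structure(list(method = "Kruskal-Wallis", statistic = 0,
                          p_value = 1, pairwise = NULL),
                     class = "shape_test"))
  kt <- stats::kruskal.test(values, g)
  structure(list(method = "Kruskal-Wallis",
                 statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value), pairwise = NULL),
            class = "shape_test")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Conover-Iman post hoc comparisons
#'
#' All-pairs rank comparisons following a Kruskal-Wallis test, using the
#' Conover-Iman t-statistics computed from the pooled ranks with
#' tie-corrected variance:
#' `t_ij = (Rbar_i - Rbar_j) / sqrt(S2 * (N-1-H)/(N-k) * (1/n_i + 1/n_j))`
#' with `S2 = (sum R^2 - N (N+1)^2 / 4) / (N - 1)`, referred to a
#' Student-t distribution on N-k degrees of freedom (two-sided). With BH
#' adjustment the family is the full set of pairs of one experiment.
#'
#' @param groups named list of numeric vectors (>= 3 groups; with 2
#'   groups the function falls back to [mann_whitney()] with a warning).
#' @param adjust `"bh"` (default) or `"none"`.
#' @return data.frame: `group_i`, `group_j`, `t_statistic`, `raw_p`,
#'   `adjusted_p` (equal to `raw_p` when `adjust = "none"`).
#' @export
conover_posthoc <- function(groups, adjust = c("bh", "none")) {
  adjust <- match.arg(adjust)
  check_groups(groups)
  k <- length(groups)
  if (k < 3) {
    warning("fewer than 3 groups; falling back to Mann-Whitney")
    mw <- mann_whitney(groups[[1]], groups[[2]])
    return(data.frame(group_i = names(groups)[1],
                      group_j = names(groups)[2],
                      t_statistic = NA_real_, raw_p = mw$p_value,
                      adjusted_p = mw$p_value, stringsAsFactors = FALSE))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)                       # mid-ranks under ties
  H <- kruskal_wallis(groups)$statistic
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  n_i <- lengths(groups)
  rbar <- tapply(r, factor(g, levels = names(groups)), mean)
  pairs <- utils::combn(names(groups), 2)
  tstat <- raw <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / n_i[[i]] + 1 / n_i[[j]]))
    tstat[p] <- (rbar[[i]] - rbar[[j]]) / se
    raw[p] <- 2 * stats::pt(-abs(tstat[p]), df = N - k)
  }
  adj <- if (adjust == "bh") bh_adjust(raw) else raw
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
             t_statistic = tstat, raw_p = raw, adjusted_p = adj,
             stringsAsFactors = FALSE)
}

#' Compare CShin populations the way the shape experiments do
#'
#' Two groups: Mann-Whitney. Three or more: Kruskal-Wallis followed by
#' Conover-Iman post hoc with Benjamini-Hochberg adjustment across all
#' pairs.
#'
#' @param groups named list of numeric vectors, or a long-format
#'   data.frame with columns `group` and `value`.
#' @return `shape_test`; for >= 3 groups `pairwise` holds the post hoc
#'   table.
#' @export
compare_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  check_groups(groups)
  if (length(groups) == 2)
    return(mann_whitney(groups[[1]], groups[[2]]))
  res <- kruskal_wallis(groups)
  res$pairwise <- conover_posthoc(groups, adjust = "bh")
  res
}

#' Box-and-whisker plot with all individual points
#'
#' Mirrors the presentation style of the shape experiments: one box per
#' group with jittered individual CShin values overlaid.
#'
#' @param df long-format data.frame with columns `group`, `value`.
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plot_group_box <- function(df, ylab = "CShin") {
  stopifnot(all(c("group", "value") %in% names(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}
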