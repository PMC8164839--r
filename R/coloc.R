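#' Threshold an intensity channel into a binary mask
#'
#' Pixels are foreground iff intensity is strictly greater than the
#' threshold (the signal/noise cut the mask workflow relies on). With
#' `threshold = "otsu"` the cut is chosen by Otsu's method on a 256-level
#' histogram. A no-primary-antibody control image may be supplied: the
#' same threshold must leave it (essentially) empty — more than 0.1%
#' foreground in the control raises a warning, since it means the cut
#' does not separate real signal from background staining.
#'
#' @param img numeric matrix of non-negative intensities.
#' @param threshold numeric cut, or `"otsu"`.
#' @param control optional control image (same acquisition settings).
#' @param strict if `TRUE`, an all-background result is an error rather
#'   than an empty mask.
#' @return logical matrix with attribute `threshold`.
#' @export
make_mask <- function(img, threshold = "otsu", control = NULL,
                      strict = FALSE) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (any(img < 0)) stop("intensities must be >= 0")
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) stop("cannot Otsu-threshold a constant image")
    threshold <- EBImage::otsu(img, range = rng, levels = 256L)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  mask <- img > threshold
  if (strict && !any(mask))
    stop("threshold ", threshold, " is above the image maximum: empty mask")
  if (!is.null(control)) {
    stopifnot(is.matrix(control))
    frac <- mean(control > threshold)
    if (frac > 0.001)
      warning(sprintf(
        "control image has %.2f%% foreground at threshold %g; expected an empty mask",
        100 * frac, threshold))
  }
  attr(mask, "threshold") <- as.numeric(threshold)
  mask
}

#' Pixelwise product (logical AND) of two masks
#'
#' The mask-multiplication step: the product of two binary masks outlines
#' exactly the overlapping regions of the two channels.
#'
#' @param a,b logical matrices of equal dimensions.
#' @return logical matrix.
#' @export
mask_product <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b)))
    stop("mask dimensions differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  out <- (a & b)
  attr(out, "threshold") <- NULL
  out
}

#' Count-based Manders coefficients
#'
#' `M1 = |A and B| / |A|` and `M2 = |A and B| / |B|`: the proportion of
#' positive pixels in one channel's mask that are also positive in the
#' other. This is the mask co-occurrence variant; the classical
#' intensity-weighted Manders coefficients are available with
#' `weighted = TRUE` and the two intensity images.
#'
#' @param a,b logical masks of equal dimensions.
#' @param weighted compute intensity-weighted coefficients instead.
#' @param img_a,img_b intensity images (required when `weighted`).
#' @return named numeric: `m1`, `m2`.
#' @export
manders_overlap <- function(a, b, weighted = FALSE,
                            img_a = NULL, img_b = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  n_a <- sum(a); n_b <- sum(b)
  if (n_a == 0) stop("mask A is empty: M1 undefined")
  if (n_b == 0) stop("mask B is empty: M2 undefined")
  if (!weighted) {
    ov <- sum(a & b)
    return(c(m1 = ov / n_a, m2 = ov / n_b))
  }
  stopifnot(is.matrix(img_a), is.matrix(img_b))
  c(m1 = sum(img_a[a & b]) / sum(img_a[a]),
    m2 = sum(img_b[a & b]) / sum(img_b[b]))
}

# Resolve an ROI argument into a logical selection matrix. An ROI may be
# a logical mask or a polygon (cell_contour or 2-column matrix of x,y);
# polygon ROIs select pixels whose centres fall inside (even-odd rule).
roi_select <- function(roi, dims) {
  if (is.null(roi)) return(matrix(TRUE, dims[1], dims[2]))
  if (is.matrix(roi) && is.logical(roi)) {
    stopifnot(all(dim(roi) == dims))
    return(roi)
  }
  if (inherits(roi, "cell_contour")) roi <- cbind(roi$x, roi$y)
  stopifnot(is.matrix(roi), ncol(roi) == 2)
  # pixel centres: x = col-1, y = row-1
  pts <- cbind(x = rep(seq_len(dims[2]) - 1, each = dims[1]),
               y = rep(seq_len(dims[1]) - 1, times = dims[2]))
  inside <- mgcv::in.out(rbind(roi, roi[1, ]), pts)
  matrix(inside, dims[1], dims[2])
}

#' Pearson correlation between two channels
#'
#' Sample Pearson correlation over all ROI pixels (not only
#' mask-positive ones); ranges from -1 (anti-colocalization) to +1
#' (complete colocalization).
#'
#' @param a,b numeric intensity matrices of equal dimensions.
#' @param roi optional ROI: logical mask, polygon matrix or
#'   [contour()].
#' @return correlation coefficient.
#' @export
pearson_r <- function(a, b, roi = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  sel <- roi_select(roi, dim(a))
  va <- a[sel]; vb <- b[sel]
  if (length(va) < 2) stop("ROI selects fewer than 2 pixels")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant channel within ROI: Pearson r undefined")
  stats::cor(va, vb)
}

#' Li's intensity correlation analysis
#'
#' Per pixel, `PDM = (A - mean(A)) * (B - mean(B))` (product of the
#' differences from the means). The intensity correlation quotient is
#' `ICQ = #\{PDM > 0\} / #\{PDM != 0\} - 0.5`, bounded in [-0.5, +0.5];
#' pixels with PDM exactly 0 carry no sign information and are excluded
#' from the denominator. The ++PDM mask flags pixels with both channels
#' above their means (double positives).
#'
#' @inheritParams pearson_r
#' @return list: `icq`, `pdm` (matrix, NA outside ROI), `pdm_pp_mask`
#'   (logical, FALSE outside ROI).
#' @export
li_ica <- function(a, b, roi = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  sel <- roi_select(roi, dim(a))
  va <- a[sel]; vb <- b[sel]
  if (length(va) < 2) stop("ROI selects fewer than 2 pixels")
  da <- va - mean(va); db <- vb - mean(vb)
  pdm_v <- da * db
  nz <- sum(pdm_v != 0)
  if (nz == 0) stop("all PDMs are zero: both channels constant in ROI")
  icq <- sum(pdm_v > 0) / nz - 0.5
  pdm <- matrix(NA_real_, nrow(a), ncol(a))
  pdm[sel] <- pdm_v
  pp <- matrix(FALSE, nrow(a), ncol(a))
  pp[sel] <- (da > 0) & (db > 0)
  list(icq = icq, pdm = pdm, pdm_pp_mask = pp)
}

#' Full two-channel colocalization report
#'
#' Runs the whole suite on a channel pair: threshold masks, their
#' product (overlap outline), count-based Manders M1/M2, Pearson r over
#' the ROI, and Li's ICQ with the ++PDM map.
#'
#' @param a,b numeric intensity matrices of equal dimensions.
#' @param threshold_a,threshold_b numeric cut or `"otsu"`, per channel.
#' @param roi optional ROI (see [pearson_r()]).
#' @param control_a,control_b optional control images checked at the
#'   same thresholds.
#' @return list of class `coloc_result`: `m1`, `m2`, `pearson_r`,
#'   `li_icq`, `n_a`, `n_b`, `n_overlap`, `threshold_a`, `threshold_b`,
#'   `overlap_mask`, `pdm_pp_mask`.
#' @export
coloc_report <- function(a, b, threshold_a = "otsu", threshold_b = "otsu",
                         roi = NULL, control_a = NULL, control_b = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  sel <- roi_select(roi, dim(a))
  full_a <- make_mask(a, threshold_a, control = control_a)
  full_b <- make_mask(b, threshold_b, control = control_b)
  mask_a <- full_a & sel
  mask_b <- full_b & sel
  if (!any(mask_a)) stop("channel A mask is empty within the ROI")
  if (!any(mask_b)) stop("channel B mask is empty within the ROI")
  overlap <- mask_product(mask_a, mask_b)
  m <- manders_overlap(mask_a, mask_b)
  ica <- li_ica(a, b, roi)
  structure(list(
    m1 = unname(m["m1"]), m2 = unname(m["m2"]),
    pearson_r = pearson_r(a, b, roi), li_icq = ica$icq,
    n_a = sum(mask_a), n_b = sum(mask_b), n_overlap = sum(overlap),
    threshold_a = attr(full_a, "threshold"),
    threshold_b = attr(full_b, "threshold"),
    overlap_mask = overlap, pdm_pp_mask = ica$pdm_pp_mask),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result: M1 = %.3f, M2 = %.3f, Pearson r = %.3f, Li ICQ = %.3f\n",
    x$m1, x$m2, x$pearson_r, x$li_icq))
  cat(sprintf("  n_a = %d, n_b = %d, n_overlap = %d>\n",
              x$n_a, x$n_b, x$n_overlap))
  invisible(x)
}

#' Write a coloc_result's scalar fields to CSV
#'
#' @param result a [coloc_report()] result.
#' @param path output CSV.
#' @export
write_coloc_csv <- function(result, path) {
  stopifnot(inherits(result, "coloc_result"))
  df <- data.frame(m1 = result$m1, m2 = result$m2,
                   pearson_r = result$pearson_r, li_icq = result$li_icq,
                   n_a = result$n_a, n_b = result$n_b,
                   n_overlap = result$n_overlap,
                   threshold_a = result$threshold_a,
                   threshold_b = result$threshold_b)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
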