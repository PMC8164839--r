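#' Read a single-channel image
#'
#' Reads an 8/16-bit PNG or TIFF into a numeric intensity matrix
#' (rows = y, cols = x). Multi-channel images are reduced to their first
#' channel with a message.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @param scale multiply the decoder's [0,1] values by this factor
#'   (default 255, the 8-bit convention).
#' @return numeric matrix.
#' @export
read_channel <- function(path, scale = 255) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) {
    message("multi-channel image; using channel 1")
    img <- img[, , 1]
  }
  img * scale
}

#' Write an intensity channel or mask to PNG/TIFF
#'
#' Masks (logical) are written as black/white; intensities are scaled by
#' `1/scale` into the encoder's [0,1] range and clipped.
#'
#' @param img numeric or logical matrix.
#' @param path output file; format from the extension.
#' @param scale intensity full-scale (default 255).
#' @export
write_channel <- function(img, path, scale = 255) {
  if (is.logical(img)) {
    m <- img * 1
  } else {
    m <- pmin(pmax(img / scale, 0), 1)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Write a per-cell metrics table to CSV
#'
#' @param metrics data.frame from [shape_metrics_table()].
#' @param path output CSV.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Run a two-population shape experiment
#'
#' The full shape-analysis path on named groups of contours: per-cell
#' metrics, then the group comparison appropriate for the number of
#' groups (Mann-Whitney for 2; Kruskal-Wallis + Conover-Iman + BH for
#' more).
#'
#' @param groups named list: each element a list of [contour()]s.
#' @return list: `metrics` (long data.frame with `group` column),
#'   `test` (a `shape_test`).
#' @export
run_shape_experiment <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  metrics <- do.call(rbind, lapply(names(groups), function(g) {
    df <- shape_metrics_table(groups[[g]])
    df$group <- g
    df
  }))
  samples <- split(metrics$cshin, metrics$group)
  list(metrics = metrics, test = compare_groups(samples))
}
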