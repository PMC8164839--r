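#' Cell contours
#'
#' A `cell_contour` is a closed polygon of (x, y) vertices in pixel units,
#' the unit object of all morphometry in this package. Coordinates follow
#' the image convention: pixel-centered, 0-based, x to the right and y
#' downwards. The polygon is implicitly closed (the last vertex connects
#' back to the first); duplicate consecutive vertices are dropped and the
#' orientation is normalised to counter-clockwise on construction.
#'
#' @param x,y numeric vertex coordinates (equal length, >= 3 after
#'   dropping duplicate consecutive vertices).
#' @param label free-text cell identifier.
#' @param validate if `TRUE` (default) the polygon is checked for
#'   self-intersection; generators that produce provably simple polygons
#'   (star-shaped outlines with positive radius) skip the check.
#' @return an object of class `cell_contour`: a list with elements
#'   `x`, `y`, `label`.
#' @export
contour <- function(x, y, label = "cell", validate = TRUE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("contour vertices contain NA")
  # drop duplicate consecutive vertices (incl. a repeated closing vertex)
  n <- length(x)
  if (n >= 2) {
    keep <- c(TRUE, x[-1] != x[-n] | y[-1] != y[-n])
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
      x <- x[-n]; y <- y[-n]; n <- n - 1L
    }
  }
  if (n < 3) stop("a contour needs at least 3 distinct vertices")
  a <- signed_area(x, y)
  if (abs(a) < .Machine$double.eps * max(1, max(abs(x)), max(abs(y)))^2)
    stop("degenerate contour: zero signed area")
  if (a < 0) { x <- rev(x); y <- rev(y) }   # normalise to counter-clockwise
  if (validate && polygon_self_intersects(x, y))
    stop("contour is self-intersecting")
  structure(list(x = x, y = y, label = as.character(label)),
            class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour '%s': %d vertices, area %.2f px^2>\n",
              x$label, length(x$x), polygon_area(x)))
  invisible(x)
}

as_contour <- function(obj) {
  if (inherits(obj, "cell_contour")) return(obj)
  stop("expected a cell_contour")
}

# Shoelace signed area (counter-clockwise positive in mathematical axes;
# we only use |area| and the sign for orientation bookkeeping).
signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Strict proper-crossing test over all edge pairs, vectorised in blocks to
# bound memory on dense contours. Shared endpoints of adjacent edges give a
# zero cross product and are excluded by the strict inequalities.
polygon_self_intersects <- function(x, y, block = 256L) {
  n <- length(x)
  j <- c(2:n, 1L)
  ax <- x; ay <- y; bx <- x[j]; by <- y[j]
  ex <- bx - ax; ey <- by - ay
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    idx <- lo:hi
    m <- length(idx)
    # cross of edge j's direction with endpoints of edge i (and vice versa)
    d1 <- outer(ax[idx], ax, "-") * rep(ey, each = m) -
          outer(ay[idx], ay, "-") * rep(ex, each = m)
    d2 <- outer(bx[idx], ax, "-") * rep(ey, each = m) -
          outer(by[idx], ay, "-") * rep(ex, each = m)
    d3 <- (rep(ax, each = m) - ax[idx]) * ey[idx] -
          (rep(ay, each = m) - ay[idx]) * ex[idx]
    d4 <- (rep(bx, each = m) - ax[idx]) * ey[idx] -
          (rep(by, each = m) - ay[idx]) * ex[idx]
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Polygon area
#'
#' Shoelace-formula area of a closed contour, positive regardless of
#' vertex orientation.
#'
#' @param contour a [contour()].
#' @return area in px^2.
#' @export
polygon_area <- function(contour) {
  contour <- as_contour(contour)
  abs(signed_area(contour$x, contour$y))
}

#' Polygon perimeter
#'
#' Sum of edge lengths including the closing edge.
#'
#' @param contour a [contour()].
#' @return perimeter in px.
#' @export
polygon_perimeter <- function(contour) {
  contour <- as_contour(contour)
  x <- contour$x; y <- contour$y
  n <- length(x); j <- c(2:n, 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# Area, centroid and normalised second central moments of the filled
# polygon, all in closed form (Green's theorem). Signed area keeps the
# moment signs consistent for either orientation.
polygon_moments <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  xj <- x[j]; yj <- y[j]
  a <- x * yj - xj * y
  A <- sum(a) / 2
  cx <- sum((x + xj) * a) / (6 * A)
  cy <- sum((y + yj) * a) / (6 * A)
  Ex2 <- sum((x^2 + x * xj + xj^2) * a) / 12
  Ey2 <- sum((y^2 + y * yj + yj^2) * a) / 12
  Exy <- sum((x * yj + 2 * x * y + 2 * xj * yj + xj * y) * a) / 24
  mxx <- Ex2 / A - cx^2
  myy <- Ey2 / A - cy^2
  mxy <- Exy / A - cx * cy
  list(area = abs(A), cx = cx, cy = cy, mxx = mxx, myy = myy, mxy = mxy)
}

#' Major axis of the moment-equivalent ellipse
#'
#' Full major-axis length of the ellipse that has the same area-normalised
#' second central moments as the filled polygon: `major = 4 * sqrt(l_max)`
#' with `l_max` the larger eigenvalue of the moment tensor. For a true
#' ellipse with semi-axes a >= b this recovers exactly 2a; for a square of
#' side s it gives `2 s / sqrt(3)` (the moment of a square is s^2/12).
#'
#' @param contour a [contour()].
#' @return full major-axis length in px.
#' @export
fit_major_axis <- function(contour) {
  contour <- as_contour(contour)
  m <- polygon_moments(contour$x, contour$y)
  tr <- m$mxx + m$myy
  det <- m$mxx * m$myy - m$mxy^2
  lmax <- tr / 2 + sqrt(pmax(tr^2 / 4 - det, 0))
  if (lmax <= 0) stop("degenerate contour: zero second moment")
  4 * sqrt(lmax)
}

#' Shape metrics and the Cell Shape Index
#'
#' Computes, on exact polygon geometry, the quantities behind the Cell
#' Shape Index for one outline:
#' \describe{
#'   \item{Circularity}{`4 * pi * Area / Perimeter^2`; 1 for a circle by
#'     the isoperimetric inequality, and very sensitive to border waviness
#'     (a serrated border inflates the perimeter at nearly constant area).}
#'   \item{Roundness}{`4 * Area / (pi * MajorAxis^2)` with the
#'     moment-equivalent-ellipse major axis; sensitive to elongation
#'     (equals minor/major for an ellipse) but blind to border texture.}
#'   \item{CShin}{`Roundness / Circularity`. Near 1 for a circle, below 1
#'     for smooth elongated outlines (epithelial-like), pushed above 1 by
#'     wavy or serrated borders (mesenchymal-like).}
#' }
#'
#' @param contour a [contour()].
#' @return a one-row data.frame: label, area, perimeter, major_axis,
#'   roundness, circularity, cshin.
#' @export
shape_metrics <- function(contour) {
  contour <- as_contour(contour)
  A <- polygon_area(contour)
  P <- polygon_perimeter(contour)
  major <- fit_major_axis(contour)
  circ <- 4 * pi * A / P^2
  round_ <- 4 * A / (pi * major^2)
  data.frame(label = contour$label, area = A, perimeter = P,
             major_axis = major, roundness = round_, circularity = circ,
             cshin = round_ / circ, stringsAsFactors = FALSE)
}

#' Shape metrics for a list of contours
#'
#' @param contours list of [contour()] objects.
#' @return data.frame with one row per contour.
#' @export
shape_metrics_table <- function(contours) {
  do.call(rbind, lapply(contours, shape_metrics))
}

#' Trace contours from a binary or labelled mask
#'
#' Extracts one sub-pixel contour per connected foreground component,
#' traced at the 0.5 level between foreground and background (marching
#' squares via [grDevices::contourLines()]). Components below
#' `min_area` px^2 are discarded as specks.
#'
#' Tracing a 0.5-level iso-contour on binary data cuts pixel corners at
#' 45 degrees, which inflates the perimeter of smooth shapes by several
#' percent at any resolution; a light circular moving average over the
#' traced vertices (`smooth`, odd window length, default 5) removes the
#' staircase while displacing the boundary by well under a pixel. Set
#' `smooth = 1` for the raw marching-squares polygon.
#'
#' @param mask logical or numeric matrix, rows = y (down), cols = x
#'   (right); nonzero = foreground. A labelled matrix (integer component
#'   ids) is also accepted.
#' @param min_area minimum component area in px^2 (default 50).
#' @param smooth odd moving-average window over traced vertices.
#' @return list of [contour()] objects.
#' @export
mask_to_contours <- function(mask, min_area = 50, smooth = 5) {
  stopifnot(smooth >= 1, smooth %% 2 == 1)
  m <- mask
  if (is.logical(m)) m <- m * 1L
  stopifnot(is.matrix(m))
  if (all(m == 0)) stop("empty mask: no foreground pixels")
  labels <- if (max(m) > 1) m else EBImage::bwlabel(m)
  labels <- round(labels)
  out <- list()
  for (lab in setdiff(sort(unique(as.vector(labels))), 0)) {
    comp <- (labels == lab) * 1
    if (sum(comp) < min_area) next
    # pad so the iso-contour closes; grid coordinates are pixel centres,
    # 0-based, row index = y, col index = x
    padded <- matrix(0, nrow(comp) + 2, ncol(comp) + 2)
    padded[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
    cl <- grDevices::contourLines(x = seq_len(nrow(padded)) - 2,
                                  y = seq_len(ncol(padded)) - 2,
                                  z = padded, levels = 0.5)
    if (!length(cl)) next
    # keep the longest loop of the component (holes are not modelled)
    lens <- vapply(cl, function(l) length(l$x), integer(1))
    loop <- cl[[which.max(lens)]]
    # contourLines' x follows our row (y) axis, its y our column (x) axis
    vx <- loop$y; vy <- loop$x
    if (vx[1] == vx[length(vx)] && vy[1] == vy[length(vy)]) {
      vx <- vx[-length(vx)]; vy <- vy[-length(vy)]
    }
    if (smooth > 1 && length(vx) > smooth) {
      kern <- rep(1 / smooth, smooth)
      vx <- as.numeric(stats::filter(vx, kern, circular = TRUE))
      vy <- as.numeric(stats::filter(vy, kern, circular = TRUE))
    }
    out[[length(out) + 1L]] <-
      contour(x = vx, y = vy, label = paste0("cc", lab),
              validate = FALSE)
  }
  if (!length(out)) stop("no component reaches min_area = ", min_area)
  out
}

#' Read cell outlines from a polygon CSV
#'
#' Expected columns: `label`, `vertex_index`, `x`, `y`; one row per
#' vertex, vertices ordered within each label. Coordinates are
#' pixel-centred, 0-based, x right / y down.
#'
#' @param path CSV file.
#' @return list of [contour()] objects.
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "vertex_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("polygon CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$label), function(d) {
    d <- d[order(d$vertex_index), ]
    contour(d$x, d$y, label = d$label[1])
  })
}

#' Write cell outlines to a polygon CSV
#'
#' @param contours list of [contour()] objects.
#' @param path output CSV file.
#' @export
write_polygons <- function(contours, path) {
  rows <- lapply(contours, function(ct) {
    data.frame(label = ct$label, vertex_index = seq_along(ct$x),
               x = ct$x, y = ct$y, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
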