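#' Shape specification for the outline generator
#'
#' Describes one synthetic outline: a base geometric figure plus an
#' optional border undulation. For radial shapes (circle, ellipse, blob)
#' the radius is modulated as `r(theta) = R(theta) * (1 + eps * w(k * theta))`
#' with `w` a sinusoid or a triangle wave ("serrated"); for cornered
#' shapes (square, rectangle, triangle) the perturbation is applied along
#' the outward normal of the base boundary, parameterised by arc length.
#' This emulates the smooth, taut borders of epithelial cells versus the
#' wavy, serrated outlines of mesenchymal-like cells.
#'
#' @param kind one of `"circle"`, `"ellipse"`, `"square"`,
#'   `"rectangle"`, `"triangle"`, `"blob"`.
#' @param size characteristic radius (radial shapes) or side (cornered
#'   shapes) in px.
#' @param aspect major/minor axis ratio, >= 1 (ellipse, rectangle).
#' @param wave_amplitude undulation amplitude `eps` relative to the local
#'   radius, `0 <= eps < 1`.
#' @param wave_count integer number of undulations `k` around the
#'   border; must be >= 3 when `wave_amplitude > 0`.
#' @param wave_form `"sinusoidal"` or `"serrated"` (triangle wave).
#' @param n_vertices number of polygon vertices, >= 32.
#' @param rotation rotation in radians.
#' @param seed integer controlling the blob's low-frequency lobes
#'   (ignored for other kinds).
#' @return list of class `shape_spec`.
#' @export
shape_spec <- function(kind = "circle", size = 60, aspect = 1,
                       wave_amplitude = 0, wave_count = 0,
                       wave_form = c("sinusoidal", "serrated"),
                       n_vertices = 256, rotation = 0, seed = 1L) {
  kind <- match.arg(kind, c("circle", "ellipse", "square", "rectangle",
                            "triangle", "blob"))
  wave_form <- match.arg(wave_form)
  stopifnot(size > 0, aspect >= 1, wave_amplitude >= 0, n_vertices >= 32)
  if (wave_amplitude >= 1)
    stop("wave_amplitude must be < 1 (radius stays positive)")
  if (wave_amplitude > 0 && wave_count < 3)
    stop("wave_count must be >= 3 when wave_amplitude > 0")
  structure(list(kind = kind, size = size, aspect = aspect,
                 wave_amplitude = wave_amplitude,
                 wave_count = as.integer(wave_count),
                 wave_form = wave_form,
                 n_vertices = as.integer(n_vertices),
                 rotation = rotation, seed = as.integer(seed)),
            class = "shape_spec")
}

# waveform on angle u (radians): unit-amplitude sinusoid or triangle wave
wave_fun <- function(u, form) {
  if (form == "sinusoidal") sin(u) else (2 / pi) * asin(sin(u))
}

rotate_xy <- function(x, y, phi) {
  list(x = cos(phi) * x - sin(phi) * y,
       y = sin(phi) * x + cos(phi) * y)
}

# base polygon for cornered kinds, counter-clockwise, centred at origin
base_corner_polygon <- function(kind, size, aspect) {
  switch(kind,
    square = {
      h <- size / 2
      cbind(x = c(-h, h, h, -h), y = c(-h, -h, h, h))
    },
    rectangle = {
      w <- size * sqrt(aspect) / 2; h <- size / sqrt(aspect) / 2
      cbind(x = c(-w, w, w, -w), y = c(-h, -h, h, h))
    },
    triangle = {
      r <- size / sqrt(3)   # circumradius of equilateral triangle, side = size
      th <- pi / 2 + c(0, 2, 4) * pi / 3
      cbind(x = r * cos(th), y = r * sin(th))
    })
}

#' Generate one synthetic outline
#'
#' @param spec a [shape_spec()].
#' @param label contour label.
#' @return a [contour()].
#' @export
make_shape <- function(spec, label = spec$kind) {
  stopifnot(inherits(spec, "shape_spec"))
  n <- spec$n_vertices
  eps <- spec$wave_amplitude
  k <- spec$wave_count
  if (spec$kind %in% c("circle", "ellipse", "blob")) {
    theta <- 2 * pi * (seq_len(n) - 1) / n
    a <- spec$size * sqrt(spec$aspect)
    b <- spec$size / sqrt(spec$aspect)
    if (spec$kind == "circle") { a <- spec$size; b <- spec$size }
    bx <- a * cos(theta); by <- b * sin(theta)
    if (spec$kind == "blob") {
      amp <- withr::with_seed(spec$seed, stats::runif(3, 0.04, 0.10))
      phase <- withr::with_seed(spec$seed + 1L, stats::runif(3, 0, 2 * pi))
      lobes <- 1 + amp[1] * cos(2 * theta + phase[1]) +
        amp[2] * cos(3 * theta + phase[2]) +
        amp[3] * cos(5 * theta + phase[3])
      bx <- bx * lobes; by <- by * lobes
    }
    mod <- 1 + eps * if (eps > 0) wave_fun(k * theta, spec$wave_form) else 0
    x <- bx * mod; y <- by * mod
    rot <- rotate_xy(x, y, spec$rotation)
    # star-shaped about the origin with strictly positive radius: simple
    return(contour(rot$x, rot$y, label = label, validate = FALSE))
  }
  base <- base_corner_polygon(spec$kind, spec$size, spec$aspect)
  nb <- nrow(base)
  nxt <- c(2:nb, 1L)
  edge <- cbind(base[nxt, 1] - base[, 1], base[nxt, 2] - base[, 2])
  elen <- sqrt(rowSums(edge^2))
  L <- sum(elen)
  cum <- cumsum(c(0, elen))
  # arc-length sample positions, always including the true corners
  s <- sort(unique(c(L * (seq_len(n) - 1) / n, cum[-length(cum)])))
  ei <- findInterval(s, cum, rightmost.closed = TRUE)
  t <- (s - cum[ei]) / elen[ei]
  px <- base[ei, 1] + t * edge[ei, 1]
  py <- base[ei, 2] + t * edge[ei, 2]
  # outward normal of a counter-clockwise polygon in image axes
  nxv <- edge[ei, 2] / elen[ei]
  nyv <- -edge[ei, 1] / elen[ei]
  # orient normals away from the centroid
  flip <- (px * nxv + py * nyv) < 0
  nxv[flip] <- -nxv[flip]; nyv[flip] <- -nyv[flip]
  if (eps > 0) {
    d <- sqrt(px^2 + py^2)                 # local centroid distance
    disp <- eps * d * wave_fun(2 * pi * k * s / L, spec$wave_form)
    px <- px + disp * nxv
    py <- py + disp * nyv
  }
  rot <- rotate_xy(px, py, spec$rotation)
  ct <- try(contour(rot$x, rot$y, label = label, validate = TRUE),
            silent = TRUE)
  if (inherits(ct, "try-error"))
    stop(sprintf(
      "self-intersecting outline: wave_amplitude %.3g too large for wave_count %d on a %s",
      eps, k, spec$kind))
  ct
}

#' Population presets
#'
#' Parameter spreads emulating the two morphology classes the Cell Shape
#' Index separates: `"epithelial"` — smooth-bordered, moderately
#' elongated outlines (CShin below 1); `"mesenchymal"` — the same
#' elongation with a wavy, high-frequency border (CShin above 1).
#'
#' @param preset `"epithelial"` or `"mesenchymal"`.
#' @return list with elements `base` (a [shape_spec()]) and `jitter`
#'   (ranges understood by [make_population()]).
#' @export
population_preset <- function(preset = c("epithelial", "mesenchymal")) {
  preset <- match.arg(preset)
  base <- shape_spec(kind = "ellipse", size = 60, n_vertices = 512)
  jitter <- list(size = c(45, 75), aspect = c(1.2, 2.0),
                 rotation = c(0, 2 * pi))
  if (preset == "mesenchymal") {
    jitter$wave_amplitude <- c(0.08, 0.18)
    jitter$wave_count <- c(10L, 20L)
  }
  list(base = base, jitter = jitter)
}

#' Generate a population of synthetic outlines
#'
#' Draws `n` contours from a base spec with independently jittered
#' parameters; a pure function of `(base, jitter, seed)` — reruns are
#' bit-identical and no global RNG state leaks.
#'
#' @param n number of contours.
#' @param base a [shape_spec()] giving defaults.
#' @param jitter named list of ranges `c(lo, hi)` for any of `size`,
#'   `aspect`, `wave_amplitude`, `wave_count` (integer range),
#'   `rotation`.
#' @param seed integer seed.
#' @param label_prefix labels are `<prefix>_<i>`.
#' @return list of [contour()] objects.
#' @export
make_population <- function(n, base, jitter = list(), seed = 1L,
                            label_prefix = "cell") {
  stopifnot(n >= 1, inherits(base, "shape_spec"))
  draw <- function(range, integer = FALSE) {
    v <- stats::runif(1, range[1], range[2])
    if (integer) v <- floor(stats::runif(1, range[1], range[2] + 1))
    v
  }
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sp <- base
      if (!is.null(jitter$size)) sp$size <- draw(jitter$size)
      if (!is.null(jitter$aspect)) sp$aspect <- draw(jitter$aspect)
      if (!is.null(jitter$wave_amplitude))
        sp$wave_amplitude <- draw(jitter$wave_amplitude)
      if (!is.null(jitter$wave_count)) {
        sp$wave_count <- as.integer(draw(jitter$wave_count, integer = TRUE))
        if (sp$wave_amplitude > 0 && sp$wave_count < 3)
          sp$wave_count <- 3L
      }
      if (!is.null(jitter$rotation)) sp$rotation <- draw(jitter$rotation)
      make_shape(sp, label = sprintf("%s_%03d", label_prefix, i))
    })
  })
}

#' Preset population with per-cell CShin
#'
#' Convenience wrapper: generate a preset population and return its
#' metrics table.
#'
#' @param preset `"epithelial"` or `"mesenchymal"`.
#' @param n population size.
#' @param seed integer seed.
#' @return data.frame of [shape_metrics()] rows with a `group` column.
#' @export
preset_population_metrics <- function(preset, n = 100, seed = 1L) {
  p <- population_preset(preset)
  cells <- make_population(n, p$base, p$jitter, seed = seed,
                           label_prefix = preset)
  df <- shape_metrics_table(cells)
  df$group <- preset
  df
}

#' Rasterize a contour onto a pixel grid
#'
#' A pixel is foreground iff its centre lies inside the polygon
#' (even-odd rule). Pixel centres are at integer coordinates, 0-based,
#' x right / y down; the contour is used as-is (no recentring), so
#' translate it onto the canvas first if needed.
#'
#' @param contour a [contour()].
#' @param image_size `c(ny, nx)` or a single integer for a square
#'   canvas.
#' @return logical matrix (rows = y, cols = x).
#' @export
rasterize <- function(contour, image_size) {
  contour <- as_contour(contour)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  ny <- image_size[1]; nx <- image_size[2]
  if (min(contour$x) < -0.5 || max(contour$x) > nx - 0.5 ||
      min(contour$y) < -0.5 || max(contour$y) > ny - 0.5)
    stop("contour extends outside the canvas")
  mask <- roi_select(cbind(contour$x, contour$y), c(ny, nx))
  if (!any(mask))
    warning("contour encloses no pixel centres: empty mask")
  mask
}

#' Translate a contour
#'
#' @param contour a [contour()].
#' @param dx,dy pixel offsets.
#' @return translated [contour()].
#' @export
shift_contour <- function(contour, dx, dy) {
  contour <- as_contour(contour)
  contour$x <- contour$x + dx
  contour$y <- contour$y + dy
  contour
}

#' Belt-pair specification
#'
#' Describes a synthetic two-channel image pair emulating junction-belt
#' micrographs: channel A stains the whole circumferential belt (an
#' annulus), channel B stains a contiguous arc subset of the belt
#' covering a known fraction `rho` of A's foreground pixels (plus,
#' optionally, an off-belt B-only disc), and both channels receive
#' additive Gaussian noise. Because the co-occurring fraction is defined
#' on A's foreground, `rho` is directly the expected count-based M1.
#'
#' @param image_size canvas side in px (square).
#' @param radius belt centreline radius in px.
#' @param width belt width in px.
#' @param rho target co-occurrence fraction in [0, 1].
#' @param fg_intensity,bg_intensity foreground/background intensities
#'   (`fg > bg >= 0`).
#' @param noise_sd additive Gaussian noise sd.
#' @param n_arcs number of contiguous B arcs the covered fraction is
#'   split into.
#' @param b_off_frac size of the off-belt B-only disc, as a fraction of
#'   A's foreground count (0 disables it).
#' @param seed integer seed.
#' @return list of class `belt_pair_spec`.
#' @export
belt_pair_spec <- function(image_size = 256, radius = 90, width = 14,
                           rho = 0.6, fg_intensity = 200,
                           bg_intensity = 20, noise_sd = 10,
                           n_arcs = 2, b_off_frac = 0, seed = 1L) {
  stopifnot(rho >= 0, rho <= 1, fg_intensity > bg_intensity,
            bg_intensity >= 0, noise_sd >= 0, n_arcs >= 1,
            b_off_frac >= 0, radius + width / 2 < image_size / 2)
  structure(list(image_size = as.integer(image_size), radius = radius,
                 width = width, rho = rho, fg_intensity = fg_intensity,
                 bg_intensity = bg_intensity, noise_sd = noise_sd,
                 n_arcs = as.integer(n_arcs), b_off_frac = b_off_frac,
                 seed = as.integer(seed)),
            class = "belt_pair_spec")
}

#' Generate a two-channel belt image pair with ground truth
#'
#' @param spec a [belt_pair_spec()].
#' @return list of class `belt_pair`: `channel_a`, `channel_b` (numeric
#'   matrices), `truth_a`, `truth_b` (logical ground-truth masks),
#'   `spec`.
#' @export
make_belt_pair <- function(spec) {
  stopifnot(inherits(spec, "belt_pair_spec"))
  S <- spec$image_size
  cx <- (S - 1) / 2; cy <- (S - 1) / 2
  xs <- matrix(rep(seq_len(S) - 1, each = S), S, S)   # col index = x
  ys <- matrix(rep(seq_len(S) - 1, times = S), S, S)  # row index = y
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  belt <- d >= spec$radius - spec$width / 2 &
          d <= spec$radius + spec$width / 2
  n_belt <- sum(belt)
  if (n_belt == 0) stop("belt is empty: no pixels in the annulus")
  withr::with_seed(spec$seed, {
    truth_a <- belt
    # order belt pixels by angle; B covers rho of them in contiguous arcs
    ang <- atan2(ys[belt] - cy, xs[belt] - cx)
    ord <- order(ang)
    n_cover <- round(spec$rho * n_belt)
    covered <- rep(FALSE, n_belt)
    if (n_cover > 0) {
      per_arc <- diff(round(seq(0, n_cover, length.out = spec$n_arcs + 1)))
      starts <- sort(sample.int(n_belt, spec$n_arcs))
      for (j in seq_len(spec$n_arcs)) {
        if (per_arc[j] == 0) next
        run <- ((starts[j] + seq_len(per_arc[j]) - 2) %% n_belt) + 1
        covered[run] <- TRUE
      }
      # arcs may wrap onto each other; top up from uncovered positions
      deficit <- n_cover - sum(covered)
      if (deficit > 0) {
        free <- which(!covered)
        covered[free[seq_len(deficit)]] <- TRUE
      }
    }
    truth_b <- matrix(FALSE, S, S)
    idx_belt <- which(belt)
    truth_b[idx_belt[ord][covered]] <- TRUE
    if (spec$b_off_frac > 0) {
      # B-only disc at the ring centre, off the belt
      r_off <- sqrt(spec$b_off_frac * n_belt / pi)
      truth_b <- truth_b | (d <= min(r_off, spec$radius - spec$width))
    }
    ch_a <- matrix(spec$bg_intensity, S, S)
    ch_a[truth_a] <- spec$fg_intensity
    ch_b <- matrix(spec$bg_intensity, S, S)
    ch_b[truth_b] <- spec$fg_intensity
    if (spec$noise_sd > 0) {
      ch_a <- pmax(ch_a + stats::rnorm(S * S, 0, spec$noise_sd), 0)
      ch_b <- pmax(ch_b + stats::rnorm(S * S, 0, spec$noise_sd), 0)
    }
    list(channel_a = ch_a, channel_b = ch_b,
         truth_a = truth_a, truth_b = truth_b, spec = spec) |>
      structure(class = "belt_pair")
  })
}

#' Synthetic surrogate of the human vinculin tankyrase-motif layout
#'
#' A deterministic, clearly synthetic 1066-residue protein record that
#' carries the three vinculin tankyrase-binding motifs at their published
#' coordinates — canonical RARGQG at 339-344, canonical RRQGKG at
#' 449-454, non-canonical RGLVAEG at 520-526 — embedded in a random
#' background that is post-processed so no spurious motif window exists
#' anywhere else. It stands in for the RefSeq protein (not distributed
#' with the package) so the motif scanner's positional behaviour can be
#' exercised end-to-end offline.
#'
#' @return one-row data.frame (`id`, `species`, `sequence`) compatible
#'   with [scan_tbm()].
#' @export
synthetic_vcl_record <- function() {
  aa <- protein_alphabet[protein_alphabet != "X"]
  seq <- withr::with_seed(20L, paste(sample(aa, 1066, replace = TRUE),
                                     collapse = ""))
  insert <- function(s, pos, motif)
    paste0(substring(s, 1, pos - 1), motif,
           substring(s, pos + nchar(motif)))
  seq <- insert(seq, 339, "RARGQG")
  seq <- insert(seq, 449, "RRQGKG")
  seq <- insert(seq, 520, "RGLVAEG")
  wanted <- data.frame(start = c(339L, 449L, 520L),
                       motif_class = c("canonical", "canonical",
                                       "non_canonical"),
                       end = c(344L, 454L, 526L))
  rec <- function(s) data.frame(id = "synthetic_VCL_surrogate",
                                species = "synthetic",
                                sequence = s, stringsAsFactors = FALSE)
  in_wanted_span <- function(p) any(p >= wanted$start & p <= wanted$end)
  # knock out accidental motifs by mutating whichever anchor (the leading
  # R or trailing G) lies outside the three protected spans
  repeat {
    hits <- scan_tbm(rec(seq))
    keep <- paste(hits$start, hits$motif_class) %in%
      paste(wanted$start, wanted$motif_class)
    extra <- hits[!keep, , drop = FALSE]
    if (!nrow(extra)) break
    mutated <- FALSE
    for (i in seq_len(nrow(extra))) {
      for (p in c(extra$start[i], extra$end[i])) {
        if (!in_wanted_span(p)) {
          substring(seq, p, p) <- "K"
          mutated <- TRUE
          break
        }
      }
    }
    if (!mutated) stop("cannot remove a spurious motif without touching a protected span")
  }
  rec(seq)
}
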