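# Seeded generators for synthetic sections, cells, fiber images, voxel masks
# and expansion series. Every generator is a pure function of (params, seed):
# seeds are applied inside withr::with_seed so no global RNG state leaks, and
# each result carries a machine-readable ground_truth list.

#' Synthetic midsagittal section
#'
#' Builds a half-domain section from the multi-phase model at control
#' parameter `epsilon`: the outer EGL boundary is `r(theta)`, the inner
#' boundary `r(theta) - t(theta)` for `theta` in `[0, pi]`, with anchoring
#' centers at the `q/2` thickness maxima. `epsilon = 0` yields a clean
#' semicircular annulus of thickness `r0/16`. Optional Gaussian jitter
#' emulates tracing noise; jitter that makes the boundaries cross triggers a
#' regeneration (new substream), with an error after 3 attempts.
#'
#' @param epsilon Control parameter in `[0, 1)`.
#' @param r0 Preferred radius in um (default 400, an E16.5-scale cerebellum).
#' @param n_points Points per boundary contour.
#' @param boundary_noise_sd Gaussian jitter s.d. in um (0 = noise-free).
#' @param seed Integer seed.
#' @return A `section_geometry` object: list with `outer` and `inner`
#'   contours, `base` (the straight ventricular-zone segment closing the
#'   section), `ac_positions` (arc length along the inner boundary, um),
#'   `ac_positions_outer`, `stage` label, and `ground_truth`.
#' @examples
#' g <- simulate_section(0.3, seed = 1)
#' length(g$ac_positions)  # 3 anchoring centers
#' @export
simulate_section <- function(epsilon, r0 = 400, n_points = 800,
                             boundary_noise_sd = 0, seed = 1) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)", call. = FALSE)
  params <- params_at_epsilon(epsilon, r0 = r0)
  shape <- model_shape(params, n_theta = n_points, domain = "half")
  for (attempt in 1:3) {
    g <- withr::with_seed(seed + (attempt - 1L) * 1000003L,
                          build_section(shape, params, boundary_noise_sd))
    if (!is.null(g)) {
      g$ground_truth$seed <- seed
      g$ground_truth$attempt <- attempt
      return(g)
    }
    warning("boundary jitter caused contour crossing; regenerating", call. = FALSE)
  }
  stop("contours still cross after 3 regeneration attempts; ",
       "reduce boundary_noise_sd", call. = FALSE)
}

build_section <- function(shape, params, noise_sd) {
  th <- shape$theta
  outer <- tibble::tibble(x = shape$r * cos(th), y = shape$r * sin(th))
  inner <- tibble::tibble(x = shape$inner * cos(th), y = shape$inner * sin(th))
  if (noise_sd > 0) {
    outer$x <- outer$x + stats::rnorm(nrow(outer), 0, noise_sd)
    outer$y <- outer$y + stats::rnorm(nrow(outer), 0, noise_sd)
    inner$x <- inner$x + stats::rnorm(nrow(inner), 0, noise_sd)
    inner$y <- inner$y + stats::rnorm(nrow(inner), 0, noise_sd)
  }
  outer_c <- as_contour(outer, closed = FALSE)
  inner_c <- as_contour(inner, closed = FALSE)
  if (noise_sd > 0) {
    # boundaries are sampled on a shared theta grid: a crossing shows up as an
    # inner radius reaching or exceeding the outer radius at the same index
    ro <- sqrt(outer$x^2 + outer$y^2)
    ri <- sqrt(inner$x^2 + inner$y^2)
    d <- dist_to_polyline(inner$x, inner$y, outer$x, outer$y)
    if (any(ri >= ro) || any(d$distance < 1e-6)) return(NULL)
  }
  # anchoring centers at interior thickness maxima
  imax <- local_maxima_indices(shape$t)
  if (params$At == 0) imax <- integer(0)
  s_inner <- cum_arc_length(inner$x, inner$y)
  s_outer <- cum_arc_length(outer$x, outer$y)
  gt <- list(
    generator = "section",
    epsilon = params$epsilon, r0 = params$r0, q = params$q,
    t0 = params$t0, At = params$At,
    at_over_t0 = if (params$t0 > 0) params$At / params$t0 else 0,
    fold_count = length(imax),
    ac_theta = th[imax],
    boundary_noise_sd = noise_sd,
    n_points = nrow(outer)
  )
  structure(list(
    outer = outer_c, inner = inner_c,
    base = tibble::tibble(x = c(outer$x[1], outer$x[nrow(outer)]),
                          y = c(outer$y[1], outer$y[nrow(outer)])),
    ac_positions = s_inner[imax],
    ac_positions_outer = s_outer[imax],
    stage = 15.5 + params$epsilon / 0.3,
    ground_truth = gt
  ), class = "section_geometry")
}

#' @export
print.section_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<section geometry: stage E%.1f (epsilon %.3g), %d + %d boundary points, ",
    "%d anchoring centers>\n"),
    x$stage, x$ground_truth$epsilon, nrow(x$outer), nrow(x$inner),
    length(x$ac_positions)))
  invisible(x)
}

# Closed polygon of the EGL band (outer boundary forward, inner reversed).
egl_band_polygon <- function(geometry) {
  rbind(as.matrix(geometry$outer[, c("x", "y")]),
        as.matrix(geometry$inner[nrow(geometry$inner):1, c("x", "y")]))
}

#' Synthetic labeled cells in the EGL band
#'
#' Places nuclei uniformly (Poisson number) in the EGL band of a section and
#' labels them the way proliferation sections are scored: every cell is
#' DAPI+, P27 is Bernoulli(`p27_rate`) (post-mitotic cells), and EdU is
#' Bernoulli(`edu_rate`) among P27- cells only, so the generating EdU rate is
#' defined on the same denominator as the measured S-phase index
#' EdU+/(DAPI+, P27-).
#'
#' @param geometry A [simulate_section()] object.
#' @param density Cells per 1000 um^2 of EGL band.
#' @param edu_rate Probability that an eligible (P27-) cell is EdU+.
#' @param p27_rate Probability that a cell is P27+.
#' @param seed Integer seed.
#' @return A tibble of class `cell_table`: `x`, `y` (um), logical `dapi`,
#'   `edu`, `p27`, and `region` (compartment between anchoring centers),
#'   with a `ground_truth` attribute.
#' @export
simulate_cells <- function(geometry, density = 20, edu_rate = 0.35,
                           p27_rate = 0.3, seed = 1) {
  stopifnot(inherits(geometry, "section_geometry"))
  if (edu_rate < 0 || edu_rate > 1 || p27_rate < 0 || p27_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  poly <- egl_band_polygon(geometry)
  area <- abs(shoelace_area(poly[, 1], poly[, 2]))
  if (area <= 0) stop("EGL band has zero area", call. = FALSE)
  withr::with_seed(seed, {
    n <- stats::rpois(1, density * area / 1000)
    pts <- matrix(numeric(0), 0, 2)
    bb <- apply(poly, 2, range)
    while (nrow(pts) < n) {
      m <- max(2L * (n - nrow(pts)), 100L)
      cand <- cbind(stats::runif(m, bb[1, 1], bb[2, 1]),
                    stats::runif(m, bb[1, 2], bb[2, 2]))
      keep <- points_in_polygon(cand, poly)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    p27 <- stats::runif(n) < p27_rate
    edu <- !p27 & stats::runif(n) < edu_rate
    theta <- atan2(pts[, 2], pts[, 1])
    breaks <- c(0, geometry$ground_truth$ac_theta, pi)
    region <- paste0("R", findInterval(theta, breaks, rightmost.closed = TRUE))
    out <- tibble::tibble(x = pts[, 1], y = pts[, 2], dapi = TRUE,
                          edu = edu, p27 = p27, region = region)
    class(out) <- c("cell_table", class(out))
    attr(out, "ground_truth") <- list(
      generator = "cells", seed = seed, density = density,
      edu_rate = edu_rate, p27_rate = p27_rate, n_cells = n,
      band_area = area
    )
    out
  })
}

#' Synthetic glial-fiber image tile
#'
#' Renders a confocal-like intensity tile around an anchoring center: the EGL
#' outer edge crosses the tile, and bright fiber segments run inward from the
#' edge, roughly radially, at prescribed per-bin crossing counts over a
#' Gaussian noise background. The signal-to-noise ratio is defined as (peak
#' fiber amplitude) / (background noise s.d.). Exact crossing arc positions
#' are recorded in the ground truth.
#'
#' @param geometry A [simulate_section()] object; the tile is centered on the
#'   middle anchoring center (or the apex for an unfolded section).
#' @param fibers_per_bin Integer vector of crossing counts, one per 50 um bin
#'   (middle bin centered at the AC).
#' @param fiber_width Gaussian cross-profile s.d. x 2 of a fiber, um.
#' @param snr Peak fiber amplitude over background noise s.d.
#' @param pixel_size um per pixel.
#' @param seed Integer seed.
#' @param bin_width Bin width along the edge, um.
#' @param depth Rendered fiber length into the tissue, um.
#' @return A `fiber_image` object: list with `intensity` (matrix, rows are
#'   image y), `pixel_size`, `edge` (tibble of outer-edge points in image um
#'   coordinates), `ac_position` (arc length of the AC along the edge) and
#'   `ground_truth`.
#' @export
simulate_fiber_image <- function(geometry, fibers_per_bin = rep(4L, 7),
                                 fiber_width = 2, snr = 5, pixel_size = 0.5,
                                 seed = 1, bin_width = 50, depth = 90) {
  stopifnot(inherits(geometry, "section_geometry"))
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  n_bins <- length(fibers_per_bin)
  if (n_bins < 1L || any(fibers_per_bin < 0))
    stop("fibers_per_bin must be a non-empty vector of counts", call. = FALSE)
  withr::with_seed(seed, {
    render_fiber_tile(geometry, as.integer(fibers_per_bin), fiber_width, snr,
                      pixel_size, seed, bin_width, depth)
  })
}

render_fiber_tile <- function(geometry, fibers_per_bin, fiber_width, snr,
                              pixel_size, seed, bin_width, depth) {
  n_bins <- length(fibers_per_bin)
  outer <- geometry$outer
  s_out <- cum_arc_length(outer$x, outer$y)
  s_ac <- if (length(geometry$ac_positions_outer))
    geometry$ac_positions_outer[ceiling(length(geometry$ac_positions_outer) / 2)]
  else max(s_out) / 2
  W <- n_bins * bin_width
  margin <- 20
  # local frame at the AC: u along the surface, v into the tissue
  p0 <- c(stats::approx(s_out, outer$x, s_ac, ties = "ordered")$y,
          stats::approx(s_out, outer$y, s_ac, ties = "ordered")$y)
  eps_s <- 1
  p1 <- c(stats::approx(s_out, outer$x, s_ac + eps_s, ties = "ordered")$y,
          stats::approx(s_out, outer$y, s_ac + eps_s, ties = "ordered")$y)
  tang <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  nrm <- c(tang[2], -tang[1])
  if (sum(nrm * (colMeans(geometry$inner[, c("x", "y")]) - p0)) < 0) nrm <- -nrm
  to_local <- function(px, py) {
    cbind((px - p0[1]) * tang[1] + (py - p0[2]) * tang[2],
          (px - p0[1]) * nrm[1] + (py - p0[2]) * nrm[2])
  }
  keep <- s_out >= s_ac - W / 2 - margin & s_out <= s_ac + W / 2 + margin
  edge_loc <- to_local(outer$x[keep], outer$y[keep])
  edge_s <- s_out[keep] - s_ac
  u_min <- -W / 2 - margin; v_min <- min(edge_loc[, 2]) - margin
  nx <- ceiling((W + 2 * margin) / pixel_size)
  ny <- ceiling((max(edge_loc[, 2]) + depth + 2 * margin - v_min) / pixel_size)
  amp <- 1; bg <- 1; noise_sd <- amp / snr
  img <- matrix(bg + stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
  # fiber crossings: jittered grid inside each bin
  crossings <- list()
  for (k in seq_len(n_bins)) {
    m <- fibers_per_bin[k]
    if (m == 0L) next
    ctr <- (k - (n_bins + 1) / 2) * bin_width
    pos <- ctr + ((seq_len(m) - 0.5) / m - 0.5) * bin_width * 0.85 +
      stats::runif(m, -1, 1) * bin_width / (4 * m + 4)
    crossings[[k]] <- pos
  }
  cross_all <- unlist(crossings) %||% numeric(0)
  sigma_f <- fiber_width / 2
  ui <- (seq_len(nx) - 0.5) * pixel_size + u_min
  vi <- (seq_len(ny) - 0.5) * pixel_size + v_min
  for (sc in cross_all) {
    a0 <- c(stats::approx(edge_s, edge_loc[, 1], sc, ties = "ordered")$y,
            stats::approx(edge_s, edge_loc[, 2], sc, ties = "ordered")$y)
    a1 <- c(stats::approx(edge_s, edge_loc[, 1], sc + eps_s, ties = "ordered")$y,
            stats::approx(edge_s, edge_loc[, 2], sc + eps_s, ties = "ordered")$y)
    tv <- (a1 - a0) / sqrt(sum((a1 - a0)^2))
    nv <- c(tv[2], -tv[1]); if (nv[2] < 0) nv <- -nv  # inward = +v side
    b0 <- a0 - 2 * nv; b1 <- a0 + (depth - 2) * nv
    cols <- which(ui >= min(b0[1], b1[1]) - 4 * sigma_f &
                  ui <= max(b0[1], b1[1]) + 4 * sigma_f)
    rows <- which(vi >= min(b0[2], b1[2]) - 4 * sigma_f &
                  vi <= max(b0[2], b1[2]) + 4 * sigma_f)
    if (!length(cols) || !length(rows)) next
    uu <- matrix(ui[cols], length(rows), length(cols), byrow = TRUE)
    vv <- matrix(vi[rows], length(rows), length(cols))
    d <- seg_dist(uu, vv, b0, b1)
    img[rows, cols] <- img[rows, cols] + amp * exp(-d^2 / (2 * sigma_f^2))
  }
  edge_img <- tibble::tibble(x = edge_loc[, 1] - u_min, y = edge_loc[, 2] - v_min)
  s_edge <- cum_arc_length(edge_img$x, edge_img$y)
  ac_pos <- stats::approx(edge_s, s_edge, 0, ties = "ordered")$y
  structure(list(
    intensity = img, pixel_size = pixel_size, edge = edge_img,
    ac_position = ac_pos,
    ground_truth = list(
      generator = "fiber_image", seed = seed,
      fibers_per_bin = fibers_per_bin, crossing_offsets = crossings,
      fiber_width = fiber_width, snr = snr, pixel_size = pixel_size,
      bin_width = bin_width, depth = depth,
      amplitude = amp, background = bg, noise_sd = noise_sd
    )
  ), class = "fiber_image")
}

# distance from grid points (uu, vv) to segment b0-b1
seg_dist <- function(uu, vv, b0, b1) {
  d <- b1 - b0
  len2 <- sum(d^2)
  tt <- ((uu - b0[1]) * d[1] + (vv - b0[2]) * d[2]) / len2
  tt <- pmin(1, pmax(0, tt))
  sqrt((uu - (b0[1] + tt * d[1]))^2 + (vv - (b0[2] + tt * d[2]))^2)
}

#' @export
print.fiber_image <- function(x, ...) {
  cat(sprintf("<fiber image: %d x %d px at %.3g um/px, %d fibers in %d bins>\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              sum(x$ground_truth$fibers_per_bin),
              length(x$ground_truth$fibers_per_bin)))
  invisible(x)
}

#' Synthetic ellipsoidal cell mask
#'
#' Voxelizes an ellipsoid for exercising the sphericity estimator. The ground
#' truth records the analytic sphericity (exact closed form for spheroids,
#' Thomsen approximation for triaxial ellipsoids).
#'
#' @param semi_axes Numeric triple of semi-axes in um.
#' @param voxel_size Isotropic voxel edge in um.
#' @param seed Integer seed (kept for the generator contract; the mask is
#'   deterministic given the geometry).
#' @return A list of class `ellipsoid_mask`: `mask` (3D logical array),
#'   `voxel_size` and `ground_truth` (including `sphericity`).
#' @export
simulate_ellipsoid_mask <- function(semi_axes, voxel_size = 1, seed = 1) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  if (any(semi_axes < 2 * voxel_size))
    stop("semi-axes under resolution: need at least 2 voxels each", call. = FALSE)
  n <- ceiling(2 * (semi_axes / voxel_size + 2))
  ctr <- (n + 1) / 2
  g1 <- (seq_len(n[1]) - ctr[1]) * voxel_size
  g2 <- (seq_len(n[2]) - ctr[2]) * voxel_size
  g3 <- (seq_len(n[3]) - ctr[3]) * voxel_size
  x <- array(g1, n)
  y <- aperm(array(g2, n[c(2, 1, 3)]), c(2, 1, 3))
  z <- aperm(array(g3, n[c(3, 1, 2)]), c(2, 3, 1))
  mask <- (x / semi_axes[1])^2 + (y / semi_axes[2])^2 + (z / semi_axes[3])^2 <= 1
  structure(list(
    mask = mask, voxel_size = voxel_size,
    ground_truth = list(
      generator = "ellipsoid_mask", seed = seed, semi_axes = semi_axes,
      voxel_size = voxel_size,
      volume = 4 / 3 * pi * prod(semi_axes),
      sphericity = ellipsoid_sphericity(semi_axes)
    )
  ), class = "ellipsoid_mask")
}

# Analytic sphericity: exact for spheroids, Thomsen (p = 1.6075) otherwise.
ellipsoid_sphericity <- function(axes) {
  axes <- sort(axes, decreasing = TRUE)
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  V <- 4 / 3 * pi * a * b * c
  S <- if (abs(b - c) < 1e-12 && abs(a - b) < 1e-12) {
    4 * pi * a^2
  } else if (abs(b - c) < 1e-12) {        # prolate: a > b = c
    e <- sqrt(1 - (b / a)^2)
    2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
  } else if (abs(a - b) < 1e-12) {        # oblate: a = b > c
    e <- sqrt(1 - (c / a)^2)
    2 * pi * a^2 * (1 + ((1 - e^2) / e) * atanh(e))
  } else {
    p <- 1.6075
    4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
  }
  (pi^(1 / 3) * (6 * V)^(2 / 3)) / S
}

#' Synthetic EGL-length / core-area expansion series
#'
#' Generates per-stage (length, area) pairs following a chosen expansion law:
#' `"semicircle"` puts every stage exactly on `L = sqrt(2*pi*A)` (proportional
#' growth), `"column"` on the fixed-width columnar reference, and
#' `"differential"` follows the semicircle curve up to `switch_stage` and then
#' inflates the EGL length faster than the core area grows — the signature of
#' differential expansion at folding onset.
#'
#' @param mode `"semicircle"`, `"column"` or `"differential"`.
#' @param stages Embryonic-day labels (at least 2, strictly increasing).
#' @param area0 Core area at the first stage, um^2.
#' @param growth Per-stage multiplicative area growth factor.
#' @param column_width Column width for `"column"` mode, um.
#' @param switch_stage Stage after which differential expansion begins
#'   (default: third stage).
#' @param differential_rate Fractional extra EGL length per stage past the
#'   switch.
#' @param seed Integer seed (series is deterministic; kept for the contract).
#' @return A tibble of class `expansion_series` with columns `stage`,
#'   `egl_length`, `core_area`, `region`, plus `ground_truth` attribute.
#' @export
simulate_expansion_series <- function(mode = c("semicircle", "column", "differential"),
                                      stages = c(16.5, 17.5, 18.5, 19.5),
                                      area0 = 2.5e5, growth = 1.6,
                                      column_width = 100, switch_stage = NULL,
                                      differential_rate = 0.15, seed = 1) {
  mode <- match.arg(mode)
  if (length(stages) < 2L || is.unsorted(stages, strictly = TRUE))
    stop("stages must be at least 2 strictly increasing values", call. = FALSE)
  area <- area0 * growth^(seq_along(stages) - 1)
  if (mode == "semicircle") {
    len <- reference_expansion(area)
  } else if (mode == "column") {
    len <- reference_expansion(area, "column", column_width = column_width)
  } else {
    switch_stage <- switch_stage %||% stages[min(3L, length(stages))]
    past <- pmax(0, cumsum(stages >= switch_stage))
    len <- reference_expansion(area) * (1 + differential_rate * past)
  }
  out <- tibble::tibble(stage = stages, egl_length = len, core_area = area,
                        region = "whole")
  class(out) <- c("expansion_series", class(out))
  attr(out, "ground_truth") <- list(
    generator = "expansion_series", seed = seed, mode = mode,
    area0 = area0, growth = growth, column_width = column_width,
    switch_stage = if (mode == "differential") switch_stage else NULL,
    differential_rate = if (mode == "differential") differential_rate else NULL
  )
  out
}
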