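#' Fiber density along the EGL by scan-line peak counting
#'
#' Quantifies glial-fiber crossings of the EGL from a fluorescence tile. A
#' low-order polynomial is fitted to the outer EGL edge; scan lines are laid
#' parallel to the fitted surface at successive depths beneath it; intensity
#' along each line (from the mean-normalized, Gaussian-smoothed image) is
#' scanned for peaks with min/max filters; and peak counts are averaged over
#' the scan lines within bins laid out along the contour, the middle bin
#' centered at the anchoring center.
#'
#' A point is a peak when it attains the running maximum of its neighborhood
#' and exceeds the running minimum by `peak_threshold` in mean-normalized
#' intensity units; the filter constants are held fixed across images. Scan
#' lines that would leave the image are dropped with a warning.
#'
#' @param image A `fiber_image` (see [simulate_fiber_image()]): a list with
#'   `intensity` matrix, `pixel_size` (um), `edge` (outer-edge points, image
#'   um coordinates) and optionally `ac_position`.
#' @param ac_position Arc-length position of the AC along the fitted contour,
#'   um; defaults to the image's own `ac_position`.
#' @param poly_order Order of the polynomial edge fit (4 or 5).
#' @param n_scanlines Number of scan lines beneath the surface.
#' @param scan_spacing Depth interval between scan lines, um; the first line
#'   sits one spacing beneath the surface.
#' @param bin_width Bin width along the contour, um.
#' @param smooth_sigma Gaussian image smoothing, pixels.
#' @param peak_neighborhood Min/max filter window, pixels (odd).
#' @param peak_threshold Required prominence above the local minimum, in
#'   mean-normalized intensity units.
#' @param extent Maximum |offset| of bin centers from the AC, um.
#' @return A tibble of class `fiber_density` with one row per bin: `offset`
#'   (bin center, um from the AC), `count` (mean peaks per scan line) and
#'   `n_lines`; the edge-fit RMS residual is attached as attribute
#'   `edge_fit_rms`.
#' @export
fiber_density_profile <- function(image, ac_position = NULL, poly_order = 4,
                                  n_scanlines = 5, scan_spacing = 12.2,
                                  bin_width = 50, smooth_sigma = 2,
                                  peak_neighborhood = 7, peak_threshold = 0.2,
                                  extent = 150) {
  stopifnot(is.matrix(image$intensity), image$pixel_size > 0)
  if (!poly_order %in% 4:5) stop("poly_order must be 4 or 5", call. = FALSE)
  ac_position <- ac_position %||% image$ac_position
  if (is.null(ac_position)) stop("ac_position is required", call. = FALSE)
  px <- image$pixel_size
  edge <- image$edge

  fit <- stats::lm(y ~ stats::poly(x, poly_order, raw = TRUE), data = edge)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  if (rms > 10)
    stop("polynomial edge fit residual too large (", signif(rms, 3),
         " um); edge is not polynomial-like", call. = FALSE)

  xs <- seq(min(edge$x), max(edge$x), by = px)
  ys <- stats::predict(fit, newdata = data.frame(x = xs))
  s <- cum_arc_length(xs, ys)[seq_along(xs)]
  # inward normal: +y points deeper into the tissue for an edge near the top;
  # pick the side with higher mean intensity two spacings down
  dy <- c(diff(ys), ys[length(ys)] - ys[length(ys) - 1L]) / px
  nxv <- -dy / sqrt(1 + dy^2); nyv <- 1 / sqrt(1 + dy^2)
  side_score <- function(sgn) {
    d <- n_scanlines * scan_spacing
    cx <- (xs + sgn * d * nxv) / px + 0.5
    cy <- (ys + sgn * d * nyv) / px + 0.5
    ok <- cy >= 1 & cy <= nrow(image$intensity) & cx >= 1 & cx <= ncol(image$intensity)
    inten <- if (any(ok)) mean(bilinear(image$intensity, cy[ok], cx[ok])) else -Inf
    c(room = mean(ok), intensity = inten)
  }
  sp <- side_score(1); sm <- side_score(-1)
  sgn <- if (sp["room"] != sm["room"]) {
    if (sp["room"] > sm["room"]) 1 else -1
  } else if (sp["intensity"] >= sm["intensity"]) 1 else -1

  norm_img <- image$intensity / mean(image$intensity)
  sm <- gauss_smooth_matrix(norm_img, smooth_sigma)

  offsets <- seq(-extent, extent, by = bin_width)
  counts <- matrix(NA_real_, n_scanlines, length(offsets))
  dropped <- 0L
  for (k in seq_len(n_scanlines)) {
    d <- k * scan_spacing
    lx <- xs + sgn * d * nxv
    ly <- ys + sgn * d * nyv
    col <- lx / px + 0.5
    row <- ly / px + 0.5
    if (any(row < 1 | row > nrow(sm) | col < 1 | col > ncol(sm))) {
      dropped <- dropped + 1L
      next
    }
    v <- bilinear(sm, row, col)
    rmax <- rolling_extreme(v, peak_neighborhood, max)
    rmin <- rolling_extreme(v, peak_neighborhood, min)
    is_peak <- v >= rmax & v > rmin + peak_threshold
    # collapse plateaus of the running max to single peaks
    peak_s <- s[is_peak]
    if (length(peak_s) > 1L) {
      gap <- c(Inf, diff(peak_s))
      peak_s <- peak_s[gap > peak_neighborhood * px / 2]
    }
    rel <- peak_s - ac_position
    for (j in seq_along(offsets)) {
      counts[k, j] <- sum(rel > offsets[j] - bin_width / 2 &
                          rel <= offsets[j] + bin_width / 2)
    }
  }
  if (dropped > 0L)
    warning(dropped, " scan line(s) left the image and were dropped", call. = FALSE)
  used <- stats::complete.cases(counts)
  out <- tibble::tibble(
    offset = offsets,
    count = colMeans(counts[used, , drop = FALSE]),
    n_lines = sum(used)
  )
  class(out) <- c("fiber_density", class(out))
  attr(out, "edge_fit_rms") <- rms
  out
}
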