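#' Create a tissue-boundary contour
#'
#' A contour is an ordered sequence of 2D points in micrometres describing a
#' tissue boundary on a midsagittal section: the outer or inner surface of the
#' external granule layer (EGL), or the closed outline of the cerebellar core.
#' Closed contours are stored counterclockwise and must be simple
#' (non-self-intersecting); consecutive duplicate points are rejected.
#'
#' @param points A data frame with numeric columns `x` and `y` (micrometres),
#'   one boundary point per row, in order along the boundary. Closed contours
#'   must not repeat the first point at the end.
#' @param closed Logical; `TRUE` for a closed outline, `FALSE` for an open arc
#'   such as the EGL surface between its anterior and posterior ends.
#' @param check_simple Logical; verify that a closed contour does not
#'   self-intersect. Checked exactly for contours up to 1500 points (the test
#'   is quadratic in the number of segments).
#' @return A tibble of class `fold_contour` with columns `x`, `y` and a
#'   `closed` attribute. Closed contours are reoriented counterclockwise.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)[-201]
#' circ <- as_contour(data.frame(x = cos(th), y = sin(th)), closed = TRUE)
#' contour_metrics(circ)$length
#' @export
as_contour <- function(points, closed = FALSE, check_simple = TRUE) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  x <- as.numeric(points$x)
  y <- as.numeric(points$y)
  if (anyNA(x) || anyNA(y)) stop("contour points must be finite", call. = FALSE)
  if (length(x) < 3L) stop("a contour needs at least 3 points", call. = FALSE)
  dup <- c(FALSE, diff(x) == 0 & diff(y) == 0)
  if (any(dup)) stop("contour has consecutive duplicate points", call. = FALSE)
  if (closed && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (closed) {
    if (shoelace_area(x, y) < 0) { x <- rev(x); y <- rev(y) }
    if (check_simple && length(x) <= 1500L && !is_simple_polygon(x, y))
      stop("closed contour is self-intersecting", call. = FALSE)
  }
  out <- tibble::tibble(x = x, y = y)
  class(out) <- c("fold_contour", class(out))
  attr(out, "closed") <- closed
  out
}

#' @rdname as_contour
#' @param x Object to test.
#' @export
is_contour <- function(x) inherits(x, "fold_contour")

#' @export
print.fold_contour <- function(x, ...) {
  cat(sprintf("<contour: %d points, %s, length %.6g um>\n",
              nrow(x), if (contour_is_closed(x)) "closed" else "open",
              contour_length(x)))
  NextMethod()
}

#' Is a contour closed?
#' @param contour A [as_contour()] object.
#' @return Logical scalar.
#' @export
contour_is_closed <- function(contour) isTRUE(attr(contour, "closed"))

# Exact O(n^2) segment-intersection test for polygon simplicity.
is_simple_polygon <- function(x, y) {
  n <- length(x)
  ax <- x; ay <- y
  bx <- c(x[-1], x[1]); by <- c(y[-1], y[1])
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[js], ay[js])
    d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[js], by[js])
    d3 <- cross(ax[js], ay[js], bx[js], by[js], ax[i], ay[i])
    d4 <- cross(ax[js], ay[js], bx[js], by[js], bx[i], by[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Resample a contour to uniform arc-length spacing
#'
#' Differential-geometry operations (curvature, smoothing) assume uniformly
#' spaced vertices, so contours are resampled by linear interpolation along
#' cumulative arc length first.
#'
#' @param contour A contour.
#' @param spacing Target spacing in micrometres. Ignored when `n_out` is given.
#' @param n_out Optional number of output points (overrides `spacing`).
#' @return A contour with uniformly spaced vertices.
#' @export
resample_contour <- function(contour, spacing = 1, n_out = NULL) {
  closed <- contour_is_closed(contour)
  x <- contour$x; y <- contour$y
  if (closed) { x <- c(x, x[1]); y <- c(y, y[1]) }
  s <- cum_arc_length(x, y)
  total <- s[length(s)]
  if (is.null(n_out)) n_out <- max(64L, length(contour$x), ceiling(total / spacing))
  s_new <- if (closed) seq(0, total, length.out = n_out + 1L)[-(n_out + 1L)]
           else seq(0, total, length.out = n_out)
  out <- tibble::tibble(
    x = stats::approx(s, x, xout = s_new, ties = "ordered")$y,
    y = stats::approx(s, y, xout = s_new, ties = "ordered")$y
  )
  class(out) <- c("fold_contour", class(out))
  attr(out, "closed") <- closed
  out
}

#' Gaussian-smooth a contour along arc length
#'
#' @param contour A contour (resampled to uniform spacing internally).
#' @param scale Smoothing scale in micrometres (the standard deviation of the
#'   Gaussian kernel in the arc-length domain); `0` disables smoothing.
#' @param spacing Resampling spacing in micrometres.
#' @return The smoothed, uniformly resampled contour.
#' @export
smooth_contour <- function(contour, scale = 10, spacing = NULL) {
  closed <- contour_is_closed(contour)
  L <- contour_length(contour)
  if (is.null(spacing)) spacing <- min(1, L / 512)
  rc <- resample_contour(contour, spacing = spacing)
  if (scale > 0) {
    h <- contour_length(rc) / (nrow(rc) - !closed)
    k <- gauss_kernel(scale / h)
    sm <- if (closed) smooth_circular else smooth_reflect
    rc$x <- as.numeric(sm(rc$x, k))
    rc$y <- as.numeric(sm(rc$y, k))
  }
  rc
}

contour_length <- function(contour) {
  x <- contour$x; y <- contour$y
  if (contour_is_closed(contour)) { x <- c(x, x[1]); y <- c(y, y[1]) }
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Signed curvature on a uniformly resampled contour; counterclockwise closed
# contours give positive curvature on convex (outward-bulging) arcs.
contour_curvature <- function(contour) {
  x <- contour$x; y <- contour$y
  n <- length(x)
  if (contour_is_closed(contour)) {
    ip <- c(n, 1:(n - 1L)); inx <- c(2:n, 1L)
  } else {
    ip <- c(1L, 1:(n - 1L)); inx <- c(2:n, n)
  }
  h <- mean(sqrt(diff(x)^2 + diff(y)^2))
  xp <- (x[inx] - x[ip]) / (2 * h); yp <- (y[inx] - y[ip]) / (2 * h)
  xpp <- (x[inx] - 2 * x + x[ip]) / h^2; ypp <- (y[inx] - 2 * y + y[ip]) / h^2
  k <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  if (!contour_is_closed(contour)) { k[1] <- k[2]; k[n] <- k[n - 1L] }
  k
}

#' Arc length, area and signed curvature of a contour
#'
#' EGL length is the polyline arc length of the outer surface following its
#' curvature; cerebellar (core) area is the shoelace area of the closed
#' outline. Curvature is computed on a Gaussian-smoothed, uniformly resampled
#' copy of the contour, with the sign convention that convex (outward-bulging)
#' arcs of a counterclockwise contour are positive.
#'
#' @param contour A contour created with [as_contour()].
#' @param smoothing_scale Arc-length Gaussian smoothing scale in micrometres
#'   applied before curvature estimation; `0` (default) uses the raw polyline.
#' @param area `NULL` (default) computes the area for closed contours only;
#'   `TRUE` demands it and raises an error on an open contour.
#' @return A list of class `contour_metrics`: `length` (um), `area` (um^2,
#'   `NA` for open contours), and `curvature`, a tibble with arc-length
#'   position `s`, coordinates and signed curvature per resampled point.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 2001)[-2001]
#' circ <- as_contour(data.frame(x = cos(th), y = sin(th)), closed = TRUE)
#' m <- contour_metrics(circ)
#' c(m$length, m$area)  # ~ 2*pi, pi
#' @export
contour_metrics <- function(contour, smoothing_scale = 0, area = NULL) {
  stopifnot(is_contour(contour))
  if (smoothing_scale < 0) stop("smoothing_scale must be >= 0", call. = FALSE)
  closed <- contour_is_closed(contour)
  if (isTRUE(area) && !closed)
    stop("area requested on an open contour", call. = FALSE)
  if (is_degenerate(contour)) stop("degenerate (collinear) contour", call. = FALSE)
  rc <- smooth_contour(contour, scale = smoothing_scale)
  # length on the raw polyline unless smoothing was requested (resampling a
  # polygon cuts corners and would perturb pure arc-length measurements)
  len <- if (smoothing_scale > 0) contour_length(rc) else contour_length(contour)
  a <- if (closed) abs(shoelace_area(contour$x, contour$y)) else NA_real_
  kappa <- contour_curvature(rc)
  s <- cum_arc_length(rc$x, rc$y)[seq_len(nrow(rc))]
  out <- list(
    length = len,
    area = a,
    curvature = tibble::tibble(s = s, x = rc$x, y = rc$y, curvature = kappa)
  )
  class(out) <- "contour_metrics"
  out
}

#' @export
print.contour_metrics <- function(x, ...) {
  cat(sprintf("<contour metrics: length %.6g um, area %s um^2, %d curvature samples>\n",
              x$length, format(x$area, digits = 6), nrow(x$curvature)))
  invisible(x)
}

is_degenerate <- function(contour) {
  x <- contour$x; y <- contour$y
  dx <- x - x[1]; dy <- y - y[1]
  cr <- dx[2] * dy - dy[2] * dx
  sc <- max(abs(dx), abs(dy))
  all(abs(cr) < 1e-12 * sc^2)
}

#' Folding index of the EGL outer surface
#'
#' The folding index is `100 * (1 - convex length / total length)`, where the
#' convex length is the arc length of segments whose signed curvature is
#' non-negative (within `curvature_tolerance`). A convex section scores 0; the
#' index grows as concave arcs (forming fissures) take up the surface.
#'
#' @param outer The EGL outer boundary (open arc or closed contour).
#' @param smoothing_scale Gaussian smoothing scale (um) applied along arc
#'   length before curvature extraction; default 10 um.
#' @param curvature_tolerance Curvature magnitude (1/um) below which an arc
#'   still counts as convex; guards against sign noise on straight stretches.
#' @return Folding index in percent, in `[0, 100]`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 1001)[-1001]
#' r <- 1 + 0.2 * sin(6 * th)
#' wavy <- as_contour(data.frame(x = r * cos(th), y = r * sin(th)), closed = TRUE)
#' folding_index(wavy, smoothing_scale = 0.01)
#' @export
folding_index <- function(outer, smoothing_scale = 10, curvature_tolerance = 1e-4) {
  stopifnot(is_contour(outer))
  L <- contour_length(outer)
  if (L <= 0) stop("contour has zero length", call. = FALSE)
  rc <- smooth_contour(outer, scale = smoothing_scale)
  kappa <- contour_curvature(rc)
  closed <- contour_is_closed(rc)
  x <- rc$x; y <- rc$y
  if (closed) { x <- c(x, x[1]); y <- c(y, y[1]) }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  # a segment is convex when both endpoints have curvature >= -tolerance
  kk <- if (closed) cbind(kappa, c(kappa[-1], kappa[1])) else cbind(kappa[-length(kappa)], kappa[-1])
  convex <- rowMeans(kk >= -curvature_tolerance) == 1
  total <- sum(seg)
  fi <- 100 * (1 - sum(seg[convex]) / total)
  min(max(fi, 0), 100)
}
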