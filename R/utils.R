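# Internal numerical helpers shared across modules.

# Cumulative arc length of a polyline given coordinate vectors.
cum_arc_length <- function(x, y) {
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

# Discrete Gaussian kernel with sd `sigma` expressed in samples; truncated at 4 sigma.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

# Smooth a periodic (circular) signal by kernel `k` (odd length).
smooth_circular <- function(v, k) {
  if (length(k) == 1L) return(v)
  half <- (length(k) - 1L) / 2L
  n <- length(v)
  idx <- c((n - half + 1L):n, 1L:n, 1L:half)
  stats::filter(v[idx], k, sides = 2)[(half + 1L):(half + n)]
}

# Smooth an open signal with reflected ends.
smooth_reflect <- function(v, k) {
  if (length(k) == 1L) return(v)
  half <- (length(k) - 1L) / 2L
  n <- length(v)
  half <- min(half, n - 1L)
  k <- k[seq.int((length(k) - 1L) / 2L - half + 1L, (length(k) - 1L) / 2L + half + 1L)]
  k <- k / sum(k)
  idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
  stats::filter(v[idx], k, sides = 2)[(half + 1L):(half + n)]
}

# Periodic derivative by spectral differentiation on a uniform grid over [0, 2*pi).
spectral_deriv <- function(v) {
  n <- length(v)
  kf <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))
  if (n %% 2 == 0) kf[n / 2 + 1] <- 0
  Re(stats::fft(1i * kf * stats::fft(v), inverse = TRUE)) / n
}

# Minimum distance from points (px, py) to the polyline with vertices (vx, vy).
# Returns distances and a flag marking feet clamped at the global polyline ends.
dist_to_polyline <- function(px, py, vx, vy) {
  ax <- vx[-length(vx)]; ay <- vy[-length(vy)]
  bx <- vx[-1L]; by <- vy[-1L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- .Machine$double.eps
  n_seg <- length(ax)
  dist <- numeric(length(px))
  at_end <- logical(length(px))
  for (i in seq_along(px)) {
    tpar <- ((px[i] - ax) * dx + (py[i] - ay) * dy) / len2
    tcl <- pmin(1, pmax(0, tpar))
    qx <- ax + tcl * dx; qy <- ay + tcl * dy
    d2 <- (px[i] - qx)^2 + (py[i] - qy)^2
    j <- which.min(d2)
    dist[i] <- sqrt(d2[j])
    at_end[i] <- (j == 1L && tpar[1L] < 0) || (j == n_seg && tpar[n_seg] > 1)
  }
  list(distance = dist, at_end = at_end)
}

# Point-in-polygon test; polygon as two-column matrix, points likewise.
points_in_polygon <- function(points, polygon) {
  if (nrow(points) == 0L) return(logical(0))
  mgcv::in.out(as.matrix(polygon), as.matrix(points))
}

# Signed shoelace area of a polygon given as coordinate vectors (not repeated at end).
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Rolling max / min with centered window of odd size k, edges truncated.
rolling_extreme <- function(v, k, fun) {
  half <- (k - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) fun(v[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# Separable 2D Gaussian smoothing of a matrix (reflected edges).
gauss_smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel(sigma)
  sm_cols <- function(mm) apply(mm, 2L, smooth_reflect, k = k)
  t(sm_cols(t(sm_cols(m))))
}

# Bilinear interpolation of matrix `m` at (row, col) positions (may be fractional).
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(row), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(col), 1L), nc - 1L)
  fr <- pmin(pmax(row - r0, 0), 1)
  fc <- pmin(pmax(col - c0, 0), 1)
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# Indices of interior local maxima, robust to single-sample plateaus (a crest
# sampled symmetrically between grid points gives two equal values).
local_maxima_indices <- function(v) {
  s <- sign(diff(v))
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  filled <- s[nz][pmax(cumsum(nz), 1L)]
  rise_to_fall <- which(filled[-length(filled)] > 0 & filled[-1] < 0)
  rise_to_fall + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
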