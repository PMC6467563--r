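#' Dimensionless shape factor of a half-section
#'
#' The shape factor is half the section perimeter divided by the square root
#' of half the section area. For a perfectly semicircular section it equals
#' `sqrt(2*pi) ~ 2.5066`, and it grows as the outline folds, making it a
#' compact summary of shape change during folding initiation.
#'
#' @param x An open contour spanning the half-domain outer boundary, or a
#'   [model_shape()] (for which perimeter and area are derived internally).
#' @param half_area Half-section area in um^2 (area enclosed by the outer
#'   boundary and its base). Required for the contour method.
#' @param ... Passed to methods.
#' @return Dimensionless shape factor.
#' @examples
#' th <- seq(0, pi, length.out = 400)
#' semi <- as_contour(data.frame(x = cos(th), y = sin(th)))
#' shape_factor(semi, half_area = pi / 2)  # sqrt(2*pi)
#' @export
shape_factor <- function(x, ...) UseMethod("shape_factor")

#' @rdname shape_factor
#' @export
shape_factor.fold_contour <- function(x, half_area, ...) {
  if (!is.numeric(half_area) || half_area <= 0)
    stop("half_area must be positive", call. = FALSE)
  contour_length(x) / sqrt(half_area)
}

#' @rdname shape_factor
#' @export
shape_factor.model_shape <- function(x, ...) {
  th <- x$theta; r <- x$r
  px <- r * cos(th); py <- r * sin(th)
  arc <- sum(sqrt(diff(px)^2 + diff(py)^2))
  dth <- th[2] - th[1]
  if (attr(x, "domain") == "half") {
    area <- 0.5 * trapz_uniform(r^2, dth)
    arc / sqrt(area)
  } else {
    # use half of the (closed) perimeter and half of the enclosed area
    arc_closed <- arc + sqrt((px[1] - px[length(px)])^2 + (py[1] - py[length(py)])^2)
    area <- 0.5 * sum(r^2) * dth
    (arc_closed / 2) / sqrt(area / 2)
  }
}

trapz_uniform <- function(v, h) h * (sum(v) - (v[1] + v[length(v)]) / 2)

#' Reference EGL length for proportional expansion
#'
#' If the section grows proportionally (no differential expansion), EGL length
#' and core area stay on a fixed curve. For a semicircular section the curve
#' is `L = sqrt(2*pi*A)`; for a column-shaped region of fixed width `w` the
#' exposed perimeter of a rectangle of area `A` is used.
#'
#' @param area Core area(s) in um^2 (vectorized).
#' @param mode `"semicircle"` or `"column"`.
#' @param column_width Fixed column width `w` in um (column mode only).
#' @param column_convention `"three-sided"` (default): the exposed perimeter is
#'   the two long sides plus the distal end, `L = 2A/w + w`; `"distal"`: only
#'   the distal end is exposed, `L = w` independent of area.
#' @return Predicted EGL length(s) in um.
#' @examples
#' reference_expansion(pi / 2)                        # pi (unit semicircle)
#' reference_expansion(1e4, "column", column_width = 100)  # 300
#' @export
reference_expansion <- function(area, mode = c("semicircle", "column"),
                                column_width = NULL,
                                column_convention = c("three-sided", "distal")) {
  mode <- match.arg(mode)
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  if (mode == "semicircle") return(sqrt(2 * pi * area))
  if (is.null(column_width) || column_width <= 0)
    stop("column mode requires a positive column_width", call. = FALSE)
  convention <- match.arg(column_convention)
  if (convention == "three-sided") 2 * area / column_width + column_width
  else rep(column_width, length(area))
}

#' Sphericity of a voxelized cell mask
#'
#' Sphericity is the surface area of the sphere with the same volume as the
#' object divided by the object's surface area; it is 1 for a sphere and
#' decreases as the shape elongates. Volume is the voxel count times the voxel
#' volume. Surface area is estimated with a coarea (smoothed-indicator)
#' estimator: the binary mask is Gaussian-smoothed and the gradient magnitude
#' integrated, which for objects a few tens of voxels across is accurate to
#' about 1 percent.
#'
#' @param mask 3D logical (or 0/1) array; a single connected object.
#' @param voxel_size Isotropic voxel edge length in um.
#' @param smooth_sigma Gaussian smoothing (voxels) for the surface estimator.
#' @return Dimensionless sphericity (at most 1 up to discretization error).
#' @export
sphericity <- function(mask, voxel_size = 1, smooth_sigma = 1.5) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array", call. = FALSE)
  m <- mask != 0
  nvox <- sum(m)
  if (nvox == 0L) stop("mask is empty", call. = FALSE)
  volume <- nvox * voxel_size^3
  area <- mask_surface_area(m, voxel_size, smooth_sigma)
  (pi^(1 / 3) * (6 * volume)^(2 / 3)) / area
}

# Coarea surface-area estimate: pad, Gaussian-smooth, integrate |grad|.
mask_surface_area <- function(mask, voxel_size = 1, smooth_sigma = 1.5) {
  d <- dim(mask)
  pad <- ceiling(4 * smooth_sigma) + 2L
  a <- array(0, d + 2L * pad)
  a[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask
  u <- gauss_smooth_array3(a, smooth_sigma)
  dd <- dim(u)
  gx <- (u[c(2:dd[1], dd[1]), , ] - u[c(1, 1:(dd[1] - 1L)), , ]) / 2
  gy <- (u[, c(2:dd[2], dd[2]), ] - u[, c(1, 1:(dd[2] - 1L)), ]) / 2
  gz <- (u[, , c(2:dd[3], dd[3])] - u[, , c(1, 1:(dd[3] - 1L))]) / 2
  sum(sqrt(gx^2 + gy^2 + gz^2)) * voxel_size^2
}

# Separable 3D Gaussian smoothing (zero-padded borders handled by caller).
gauss_smooth_array3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gauss_kernel(sigma)
  half <- (length(k) - 1L) / 2L
  conv1 <- function(arr) {
    d <- dim(arr)
    m <- matrix(arr, d[1], d[2] * d[3])
    mp <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    out <- stats::filter(mp, k, sides = 2)
    array(out[(half + 1L):(half + d[1]), ], d)
  }
  a <- conv1(a)
  a <- aperm(conv1(aperm(a, c(2, 3, 1))), c(3, 1, 2))
  aperm(conv1(aperm(a, c(3, 1, 2))), c(2, 3, 1))
}

#' Bulk modulus from acoustic measurements
#'
#' Scanning acoustic microscopy yields the acoustic impedance `Z` and speed of
#' sound `c` of a tissue section; the bulk modulus is their product,
#' `K = Z * c`. With `Z` in MRayl (1 MRayl = 1e6 Pa s/m) and `c` in m/s the
#' result is returned in GPa. The implied mass density `rho = Z / c` is also
#' reported.
#'
#' @param impedance Acoustic impedance in MRayl (vectorized).
#' @param speed_of_sound Speed of sound in m/s (vectorized).
#' @return A tibble with columns `impedance_mrayl`, `speed_m_s`,
#'   `bulk_modulus_gpa` and `density_kg_m3`.
#' @examples
#' bulk_modulus_from_acoustics(1.5, 1500)$bulk_modulus_gpa  # 2.25
#' @export
bulk_modulus_from_acoustics <- function(impedance, speed_of_sound) {
  if (any(impedance <= 0) || any(speed_of_sound <= 0))
    stop("impedance and speed of sound must be positive", call. = FALSE)
  tibble::tibble(
    impedance_mrayl = impedance,
    speed_m_s = speed_of_sound,
    bulk_modulus_gpa = impedance * speed_of_sound / 1000,
    density_kg_m3 = impedance / speed_of_sound * 1e6
  )
}
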