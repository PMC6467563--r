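#' Multi-phase model parameters
#'
#' The multi-phase model treats the EGL as a fluid-like layer of thickness
#' `t(theta)` riding on an incompressible core of outer radius `r(theta)`,
#' under a radial elastic constraint (stiffness `k_r`, preferred radius `r0`),
#' a growth potential on thickness (`k_t`, preferred thickness `t0`) and a
#' thickness-regularizing term (`beta`). The core area is constrained, which
#' introduces a Lagrange multiplier `mu`; the dimensionless control parameter
#' is `epsilon = mu / k_r`, which plays the role of developmental time.
#'
#' `params_from_epsilon()` applies the calibrated single-parameter family in
#' which every dimensionless parameter is slaved to `epsilon`:
#' `c = k_r/k_t = 0.06/epsilon`, `At/r0 = epsilon/9.6`,
#' `t0/r0 = epsilon/4.8`, and angular wavenumber `q = 6`. At `epsilon = 0.3`
#' this family matches the E16.5 cerebellum: thickness-oscillation amplitude
#' over mean thickness `At/t0 = 0.5` and `r0/t0 = 16`.
#'
#' @param epsilon Dimensionless `mu/k_r`, in `(0, 1)`.
#' @param r0 Preferred radius (um); the model is scale-free so the default is
#'   the dimensionless choice `r0 = 1`.
#' @param q Angular wavenumber (6 for the E16.5 cerebellum).
#' @param phi Phase of the thickness oscillation (radians).
#' @param k_r Radial stiffness setting the energy scale (default 1).
#' @return An object of class `model_params`: a list with elements `epsilon`,
#'   `c`, `at_over_r0`, `t0_over_r0`, `q`, `phi`, `r0`, and the implied
#'   `k_r`, `k_t`, `mu`, `At`, `t0`.
#' @examples
#' p <- params_from_epsilon(0.3)
#' p$At / p$t0          # 0.5
#' p$r0 / p$t0          # 16
#' @export
params_from_epsilon <- function(epsilon, r0 = 1, q = 6, phi = 0, k_r = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  model_params(
    epsilon = epsilon, c = 0.06 / epsilon,
    at_over_r0 = epsilon / 9.6, t0_over_r0 = epsilon / 4.8,
    q = q, phi = phi, r0 = r0, k_r = k_r
  )
}

#' @rdname params_from_epsilon
#' @param c Stiffness ratio `k_r / k_t`.
#' @param at_over_r0,t0_over_r0 Thickness oscillation amplitude and preferred
#'   thickness, as fractions of `r0`.
#' @export
model_params <- function(epsilon, c, at_over_r0, t0_over_r0, q = 6, phi = 0,
                         r0 = 1, k_r = 1) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)", call. = FALSE)
  if (any(c(c, at_over_r0, t0_over_r0) < 0) || t0_over_r0 <= 0 || c <= 0)
    stop("ratios must be positive", call. = FALSE)
  if (q <= 0) stop("q must be positive", call. = FALSE)
  out <- list(
    epsilon = epsilon, c = c, at_over_r0 = at_over_r0,
    t0_over_r0 = t0_over_r0, q = q, phi = phi, r0 = r0,
    k_r = k_r, k_t = k_r / c, mu = epsilon * k_r,
    At = at_over_r0 * r0, t0 = t0_over_r0 * r0
  )
  class(out) <- "model_params"
  out
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<multi-phase model parameters>\n",
    "  epsilon = %.4g, c = k_r/k_t = %.4g, q = %g, phi = %.4g\n",
    "  r0 = %.4g um, t0 = %.4g um, At = %.4g um (At/t0 = %.4g)\n"),
    x$epsilon, x$c, x$q, x$phi, x$r0, x$t0, x$At,
    if (x$t0 > 0) x$At / x$t0 else NA))
  invisible(x)
}

#' Developmental time to model control parameter
#'
#' The control parameter is assumed to grow linearly with embryonic day `T`:
#' `epsilon(T) = 0.3 * (T - 15.5)`, calibrated so E16.5 maps to
#' `epsilon = 0.3`. The sinusoidal solution exists only for `epsilon < 1`,
#' i.e. up to (but not including) `T = 15.5 + 1/0.3 ~ 18.83`.
#'
#' @param T Embryonic day(s), e.g. 16.5 (vectorized).
#' @return `epsilon` value(s).
#' @export
epsilon_of_time <- function(T) {
  eps <- 0.3 * (T - 15.5)
  if (any(eps < 0))
    stop("stage before T = 15.5 maps to negative epsilon", call. = FALSE)
  if (any(eps >= 1))
    stop("stage at or beyond T = 15.5 + 1/0.3 (~18.83) maps to epsilon >= 1, ",
         "outside the model's validity bound epsilon < 1", call. = FALSE)
  eps
}

#' Surface-to-thickness amplitude ratio
#'
#' The sinusoidal solution predicts that the surface height (radius)
#' oscillation amplitude `Ar` relates to the thickness oscillation amplitude
#' `At` as `Ar/At = epsilon / (1 - epsilon)`, which need not be large —
#' unlike elastic bilayer wrinkling.
#'
#' @param epsilon `mu/k_r`, in `[0, 1)` (vectorized).
#' @return `Ar/At` value(s).
#' @export
amplitude_ratio <- function(epsilon) {
  if (any(epsilon < 0) || any(epsilon >= 1))
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  epsilon / (1 - epsilon)
}

#' Thickness-regularization stiffness consistent with a wavenumber
#'
#' Returns `beta` such that mode `q` is the stationary wavenumber of the
#' shape equation. Two closed forms are provided: `"derived"`,
#' `q^2 = (k_t/beta) * ((1 - eps) + mu/k_t) / (1 - eps)`, obtained directly
#' from the Euler-Lagrange equations of the energy functional, and
#' `"printed"`, `q^2 = (k_t/beta) * (1 + mu/k_t) / (1 - eps)`, the form given
#' alongside the model. The two differ in the numerator; the constrained
#' numerical minimizer ([minimize_fold_energy()]) reproduces the analytic
#' sinusoid only with the derived form, which is therefore the default.
#'
#' @param params A [model_params()] object.
#' @param variant `"derived"` (default) or `"printed"`.
#' @return `beta` in energy units per radian^2.
#' @export
beta_for_q <- function(params, variant = c("derived", "printed")) {
  variant <- match.arg(variant)
  eps <- params$epsilon; kt <- params$k_t; mu <- params$mu; q <- params$q
  if (variant == "derived") (kt + mu / (1 - eps)) / q^2
  else kt * (1 + mu / kt) / ((1 - eps) * q^2)
}

#' Wavenumber selected by the fold-count relation
#'
#' Evaluates the closed-form fold-count (wavenumber) relation
#' `n = sqrt((k_t/beta) * (1 + mu/k_t) / (1 - mu/k_r))` (printed form), or
#' the directly derived variant with numerator `(1 - eps) + mu/k_t`.
#'
#' @param kt_over_beta `k_t / beta`.
#' @param mu_over_kt `mu / k_t`.
#' @param epsilon `mu / k_r`.
#' @param variant `"printed"` (default here, the published relation) or
#'   `"derived"`.
#' @return The predicted number of folds on the full circle (a positive real;
#'   integer when the parameters are mutually consistent).
#' @export
fold_count_formula <- function(kt_over_beta, mu_over_kt, epsilon,
                               variant = c("printed", "derived")) {
  variant <- match.arg(variant)
  if (epsilon >= 1) stop("epsilon must be < 1", call. = FALSE)
  num <- if (variant == "printed") 1 + mu_over_kt else (1 - epsilon) + mu_over_kt
  sqrt(kt_over_beta * num / (1 - epsilon))
}

#' Analytic model shape
#'
#' Samples the sinusoidal stationary solution of the multi-phase model:
#' `t(theta) = At * sin(q*theta + phi) + C1` with `C1 = t0` (mean thickness
#' equals the preferred thickness), and
#' `r(theta) = -(eps/(1-eps)) * At * sin(q*theta + phi) + C3` with
#' `C3 = (r0 - eps*t0)/(1-eps)` from the radial stationarity relation
#' `k_r (r - r0) = mu (r - t)`. Thickness and radius oscillate exactly out of
#' phase for `0 < eps < 1`: the EGL is thickest where the surface is lowest,
#' i.e. at the anchoring centers.
#'
#' On the half domain `theta` runs over `[0, pi]` and the phase is fixed to
#' `-pi/2` (a `-cos` profile) so the thickness slope vanishes at both ends
#' (zero-flux boundary conditions) and exactly `q/2` interior thickness maxima
#' fit, one at the domain midpoint.
#'
#' @param params A [model_params()] object.
#' @param n_theta Number of angular samples (at least `16 * q`).
#' @param domain `"full"` (periodic circle) or `"half"` (semicircular section).
#' @return A tibble of class `model_shape` with columns `theta`, `t`, `r`,
#'   `inner` (`= r - t`), and attributes `params`, `C1`, `C3`, `A0` (the core
#'   area `0.5 * integral (r - t)^2 dtheta` over the domain) and `domain`.
#' @examples
#' s <- model_shape(params_from_epsilon(0.3))
#' fold_count_model(s)  # 6
#' @export
model_shape <- function(params, n_theta = 720, domain = c("full", "half")) {
  domain <- match.arg(domain)
  stopifnot(inherits(params, "model_params"))
  if (n_theta < 16 * params$q)
    stop("n_theta must be at least 16 * q", call. = FALSE)
  eps <- params$epsilon
  phi <- if (domain == "half") -pi / 2 else params$phi
  th <- if (domain == "full") seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
        else seq(0, pi, length.out = n_theta)
  C1 <- params$t0
  C3 <- (params$r0 - eps * params$t0) / (1 - eps)
  osc <- sin(params$q * th + phi)
  t <- params$At * osc + C1
  r <- -(eps / (1 - eps)) * params$At * osc + C3
  inner <- r - t
  if (any(t <= 0)) stop("parameters produce non-positive EGL thickness", call. = FALSE)
  if (any(inner <= 0)) stop("parameters produce non-positive core radius", call. = FALSE)
  dth <- th[2] - th[1]
  A0 <- if (domain == "full") 0.5 * sum(inner^2) * dth
        else 0.5 * trapz_uniform(inner^2, dth)
  out <- tibble::tibble(theta = th, t = t, r = r, inner = inner)
  class(out) <- c("model_shape", class(out))
  attr(out, "params") <- params
  attr(out, "C1") <- C1
  attr(out, "C3") <- C3
  attr(out, "A0") <- A0
  attr(out, "domain") <- domain
  out
}

#' @export
print.model_shape <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<model shape: %s domain, epsilon = %.3g, q = %g, %d samples, A0 = %.6g>\n",
              attr(x, "domain"), p$epsilon, p$q, nrow(x), attr(x, "A0")))
  NextMethod()
}

#' Count folds of a model shape
#'
#' Counts strict local maxima of the EGL thickness `t(theta)`: on the full
#' circle a shape with wavenumber `q` has `q` maxima, on the half domain
#' `q/2`. Each thickness maximum marks an anchoring center (an inward fold).
#'
#' @param shape A [model_shape()], or a [model_params()] object (a shape is
#'   sampled internally).
#' @param ... Passed to [model_shape()] when `shape` is a parameter set.
#' @return Integer number of thickness maxima.
#' @export
fold_count_model <- function(shape, ...) {
  if (inherits(shape, "model_params")) shape <- model_shape(shape, ...)
  stopifnot(inherits(shape, "model_shape"))
  count_local_maxima(shape$t, periodic = attr(shape, "domain") == "full")
}

# Counts descents of the forward difference from rising to falling, treating
# flat runs (plateau maxima, e.g. a crest sampled symmetrically between two
# grid points) as part of the preceding slope.
count_local_maxima <- function(v, periodic = TRUE) {
  d <- if (periodic) diff(c(v, v[1])) else diff(v)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(0L)
  runs <- s[nz]
  runs <- runs[c(TRUE, diff(runs) != 0)]
  k <- sum(runs[-length(runs)] > 0 & runs[-1] < 0)
  if (periodic && runs[length(runs)] > 0 && runs[1] < 0) k <- k + 1L
  as.integer(k)
}

# Parameter family including the epsilon = 0 limit: the oscillation amplitude
# vanishes and the preferred thickness freezes at its E16.5 value t0/r0 = 1/16,
# giving a clean semicircular annulus.
params_at_epsilon <- function(epsilon, r0 = 1, q = 6, phi = 0, k_r = 1) {
  if (epsilon > 0) params_from_epsilon(epsilon, r0 = r0, q = q, phi = phi, k_r = k_r)
  else model_params(epsilon = 0, c = Inf, at_over_r0 = 0, t0_over_r0 = 0.3 / 4.8,
                    q = q, phi = phi, r0 = r0, k_r = k_r)
}

#' Energy functional of the multi-phase model
#'
#' Evaluates `E[r, t] = integral( k_r (r - r0)^2 - k_t (t - t0)^2 +
#' beta (dt/dtheta)^2 ) dtheta` on a uniform periodic grid over `[0, 2*pi)`
#' by quadrature, with a spectral (default) or centered finite-difference
#' derivative for `dt/dtheta`.
#'
#' @param r,t Sampled radius and thickness on a common uniform periodic grid.
#' @param k_r,k_t,beta Model stiffnesses.
#' @param r0,t0 Preferred radius and thickness.
#' @param deriv `"spectral"` or `"fd"`.
#' @return Scalar energy (arbitrary units).
#' @export
energy_functional <- function(r, t, k_r, k_t, beta, r0, t0,
                              deriv = c("spectral", "fd")) {
  deriv <- match.arg(deriv)
  if (length(r) != length(t)) stop("r and t grids differ in length", call. = FALSE)
  n <- length(t)
  dth <- 2 * pi / n
  dt <- if (deriv == "spectral") spectral_deriv(t)
        else (t[c(2:n, 1L)] - t[c(n, 1:(n - 1L))]) / (2 * dth)
  sum(k_r * (r - r0)^2 - k_t * (t - t0)^2 + beta * dt^2) * dth
}

#' Core area functional
#'
#' The incompressible-core constraint fixes `A0 = 0.5 * integral (r - t)^2
#' dtheta`; this evaluates the left-hand side on a uniform periodic grid.
#'
#' @inheritParams energy_functional
#' @return Core area in um^2 (or model units squared).
#' @export
core_area <- function(r, t) {
  if (length(r) != length(t)) stop("r and t grids differ in length", call. = FALSE)
  0.5 * sum((r - t)^2) * (2 * pi / length(r))
}

#' Model predictions across developmental stages
#'
#' Composes [epsilon_of_time()], [params_from_epsilon()], [model_shape()]
#' (half domain) and [shape_factor()] for a series of embryonic days,
#' producing the model's predicted shape-factor trajectory against the
#' semicircular baseline `sqrt(2*pi)`.
#'
#' @param stages Embryonic days (each must map to `epsilon` in `(0, 1)`).
#' @param r0 Preferred radius (um); dimensionless default 1.
#' @param n_theta Angular resolution per shape.
#' @return A tibble with one row per stage: `stage`, `epsilon`, `shape`
#'   (list column of [model_shape()] objects), `shape_factor`, and
#'   `shape_factor_semicircle`.
#' @export
predict_stage_series <- function(stages, r0 = 1, n_theta = 720) {
  eps <- epsilon_of_time(stages)
  shapes <- lapply(eps, function(e)
    model_shape(params_at_epsilon(e, r0 = r0), n_theta = n_theta, domain = "half"))
  tibble::tibble(
    stage = stages,
    epsilon = eps,
    shape = shapes,
    shape_factor = vapply(shapes, shape_factor, numeric(1)),
    shape_factor_semicircle = sqrt(2 * pi)
  )
}
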