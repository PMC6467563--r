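# broom-style tidiers for fitted/derived objects.

#' Tidy a model parameter set
#'
#' @param x A [model_params()] object.
#' @param ... Ignored.
#' @return A one-row tibble of the dimensionless parameters and scales.
#' @method tidy model_params
#' @export
tidy.model_params <- function(x, ...) {
  tibble::tibble(
    epsilon = x$epsilon, c = x$c, q = x$q, phi = x$phi,
    at_over_r0 = x$at_over_r0, t0_over_r0 = x$t0_over_r0,
    at_over_t0 = if (x$t0 > 0) x$At / x$t0 else NA_real_,
    r0 = x$r0, t0 = x$t0, At = x$At,
    k_r = x$k_r, k_t = x$k_t, mu = x$mu
  )
}

#' Tidy a model shape
#'
#' @param x A [model_shape()].
#' @param ... Ignored.
#' @return The shape in long form: `theta`, `quantity`, `value`.
#' @method tidy model_shape
#' @export
tidy.model_shape <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"theta",
                      names_to = "quantity", values_to = "value")
}

#' One-row summary of a model shape
#'
#' @param x A [model_shape()].
#' @param ... Ignored.
#' @return Tibble with `epsilon`, `q`, `domain`, `A0`, `C1`, `C3`,
#'   `fold_count` and `shape_factor`.
#' @method glance model_shape
#' @export
glance.model_shape <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    epsilon = p$epsilon, q = p$q, domain = attr(x, "domain"),
    A0 = attr(x, "A0"), C1 = attr(x, "C1"), C3 = attr(x, "C3"),
    fold_count = fold_count_model(x),
    shape_factor = shape_factor(x)
  )
}

#' Tidy the constrained energy minimizer
#'
#' @param x A [minimize_fold_energy()] fit.
#' @param ... Ignored.
#' @return Per-mode amplitudes of the minimizing shape.
#' @method tidy fold_energy_fit
#' @export
tidy.fold_energy_fit <- function(x, ...) x$amplitudes

#' One-row summary of the constrained energy minimizer
#'
#' @param x A [minimize_fold_energy()] fit.
#' @param ... Ignored.
#' @return Tibble with `dominant_mode`, `t_amplitude`, `energy`,
#'   `multiplier` and `constraint_residual`.
#' @method glance fold_energy_fit
#' @export
glance.fold_energy_fit <- function(x, ...) {
  tibble::tibble(
    dominant_mode = x$dominant_mode,
    t_amplitude = max(x$amplitudes$t_amplitude),
    energy = x$energy,
    multiplier = x$multiplier,
    constraint_residual = x$constraint_residual
  )
}

#' One-row summary of a thickness profile
#'
#' @param x A [thickness_profile()].
#' @param ... Ignored.
#' @return Tibble with sample count, mean thickness, oscillation amplitude
#'   over mean, and dropped-sample count.
#' @method glance thickness_profile
#' @export
glance.thickness_profile <- function(x, ...) {
  mt <- attr(x, "mean_thickness")
  tibble::tibble(
    n = nrow(x),
    mean_thickness = mt,
    amplitude_over_mean = (max(x$thickness) - min(x$thickness)) / 2 / mt,
    dropped = attr(x, "dropped")
  )
}
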