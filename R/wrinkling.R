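#' Elastic bilayer wrinkling wavelength
#'
#' For a stiff film of thickness `t` and stiffness `E_o` bonded to a softer
#' substrate of stiffness `E_i`, the planar wrinkling instability selects the
#' wavelength `lambda = 2*pi*t * (E_o / (3*E_i))^(1/3)`. This is the baseline
#' against which the cerebellar measurements are tested: reproducing the
#' observed fold spacing through wrinkling alone demands a large
#' film-to-substrate stiffness ratio.
#'
#' @param thickness Film (outer layer) thickness `t` in um (vectorized).
#' @param stiffness_outer Film stiffness `E_o` (any unit, e.g. kPa).
#' @param stiffness_inner Substrate (core) stiffness `E_i` (same unit).
#' @return Wavelength in um.
#' @examples
#' wrinkle_wavelength(25, 3, 1)  # 2*pi*25
#' @export
wrinkle_wavelength <- function(thickness, stiffness_outer, stiffness_inner) {
  check_positive(thickness = thickness, stiffness_outer = stiffness_outer,
                 stiffness_inner = stiffness_inner)
  2 * pi * thickness * (stiffness_outer / (3 * stiffness_inner))^(1 / 3)
}

#' Number of wrinkling folds
#'
#' The number of folds is the system length over the wavelength, `n = l /
#' lambda`; on a circle of radius `R` the length is the circumference
#' `l = 2*pi*R`, so `n = (R/t) * (3*E_i/E_o)^(1/3)` — inversely proportional
#' to the film thickness.
#'
#' @inheritParams wrinkle_wavelength
#' @param length System length `l` in um; give either `length` or `radius`.
#' @param radius Circle radius `R` in um (`l = 2*pi*R`).
#' @return Number of folds (dimensionless, not rounded).
#' @examples
#' fold_number(25, 50, 1, radius = 16 * 25)  # ~ 6.26
#' @export
fold_number <- function(thickness, stiffness_outer, stiffness_inner,
                        length = NULL, radius = NULL) {
  if (is.null(length) == is.null(radius))
    stop("give exactly one of `length` or `radius`", call. = FALSE)
  l <- if (is.null(length)) 2 * pi * radius else length
  check_positive(l = l)
  l / wrinkle_wavelength(thickness, stiffness_outer, stiffness_inner)
}

#' Stiffness ratio required for a target fold count
#'
#' Inverts the circular fold-number relation: to obtain `n` folds on a circle
#' whose radius is `R_over_t` film thicknesses, the film-to-substrate
#' stiffness ratio must be `E_o/E_i = 3 * (R_over_t / n)^3`. For the E16.5
#' cerebellum (`n = 6`, `R/t = 16`) this gives about 57, far above the
#' measured near-unity modulus contrast.
#'
#' @param n Target fold count (vectorized).
#' @param R_over_t Radius-to-thickness ratio.
#' @return Required stiffness ratio `E_o / E_i`.
#' @examples
#' required_stiffness_ratio(6, 16)  # 3 * (16/6)^3 ~ 56.9
#' @export
required_stiffness_ratio <- function(n, R_over_t) {
  check_positive(n = n, R_over_t = R_over_t)
  3 * (R_over_t / n)^3
}

#' Wrinkling report over a parameter grid
#'
#' Tabulates wavelength, fold number and the stiffness ratio required to
#' reach a target fold count for every row of a bilayer parameter grid.
#'
#' @param params A data frame with columns `thickness`, `stiffness_outer`,
#'   `stiffness_inner` and either `radius` or `length` (um).
#' @param fold_target Fold count used for the required-ratio column.
#' @return The input tibble with `wavelength`, `n_folds` and
#'   `required_ratio` columns added.
#' @export
wrinkling_report <- function(params, fold_target = 6) {
  stopifnot(is.data.frame(params))
  need <- c("thickness", "stiffness_outer", "stiffness_inner")
  if (!all(need %in% names(params)))
    stop("params needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  has_radius <- "radius" %in% names(params)
  if (!has_radius && !("length" %in% names(params)))
    stop("params needs a `radius` or `length` column", call. = FALSE)
  l <- if (has_radius) 2 * pi * params$radius else params$length
  lam <- wrinkle_wavelength(params$thickness, params$stiffness_outer,
                            params$stiffness_inner)
  rt <- l / (2 * pi * params$thickness)
  dplyr::mutate(tibble::as_tibble(params),
                wavelength = lam,
                n_folds = l / lam,
                required_ratio = required_stiffness_ratio(fold_target, rt))
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] <= 0))
      stop(nm, " must be positive", call. = FALSE)
  }
  invisible(TRUE)
}
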