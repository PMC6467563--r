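# ggplot2 autoplot methods for the package's result types.

#' Plot a section geometry
#'
#' @param object A `section_geometry`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot section_geometry
#' @export
autoplot.section_geometry <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$outer), boundary = "outer EGL"),
    dplyr::mutate(tibble::as_tibble(object$inner), boundary = "inner EGL"),
    dplyr::mutate(tibble::as_tibble(object$base), boundary = "base")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$boundary)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Section at E%.1f", object$stage)) +
    ggplot2::theme_minimal()
}

#' Plot a thickness profile
#'
#' @param object A [thickness_profile()].
#' @param normalized Plot thickness / mean (default) or raw thickness.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot thickness_profile
#' @export
autoplot.thickness_profile <- function(object, normalized = TRUE, ...) {
  y <- if (normalized) "normalized" else "thickness"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = if (normalized) 1 else
      attr(object, "mean_thickness"), linetype = "dashed") +
    ggplot2::labs(x = "arc length along inner EGL (µm)",
                  y = if (normalized) "thickness / mean" else "thickness (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a model shape
#'
#' Shows the outer surface and inner boundary in section coordinates.
#'
#' @param object A [model_shape()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot model_shape
#' @export
autoplot.model_shape <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(x = object$r * cos(object$theta),
                   y = object$r * sin(object$theta), boundary = "outer EGL"),
    tibble::tibble(x = object$inner * cos(object$theta),
                   y = object$inner * sin(object$theta), boundary = "inner EGL")
  )
  p <- attr(object, "params")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$boundary)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Multi-phase model shape (epsilon = %.2g, q = %g)",
                                  p$epsilon, p$q),
                  x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a fiber density profile
#'
#' @param object A [fiber_density_profile()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot fiber_density
#' @export
autoplot.fiber_density <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$count)) +
    ggplot2::geom_col(width = 40) +
    ggplot2::labs(x = "offset from AC (µm)", y = "fibers per bin") +
    ggplot2::theme_minimal()
}

#' Plot a pipeline report
#'
#' Shape-factor trajectories: semicircular baseline, model prediction and
#' measurement, by stage.
#'
#' @param object A [run_full_analysis()] report.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot fold_report
#' @export
autoplot.fold_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$comparison,
                           dplyr::starts_with("shape_factor"),
                           names_to = "source", values_to = "shape_factor")
  d$source <- sub("shape_factor_", "", d$source)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$shape_factor,
                                  colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "embryonic day", y = "shape factor") +
    ggplot2::theme_minimal()
}
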