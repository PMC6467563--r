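#' Configuration for a full generate-measure-model-compare run
#'
#' Collects every tunable parameter of the pipeline with its default, so a
#' run is reproducible from the config alone. The config can be serialized
#' to / restored from JSON.
#'
#' @param stages Embryonic days to analyse.
#' @param seed Master seed; all per-stage generator seeds derive from it.
#' @param r0 Preferred radius of the synthetic sections, um.
#' @param n_points Points per synthetic boundary contour.
#' @param boundary_noise_sd Boundary jitter s.d., um.
#' @param thickness_spacing Thickness sampling interval, um.
#' @param smoothing_scale Curvature smoothing scale, um.
#' @param curvature_tolerance Convexity tolerance, 1/um.
#' @param wrinkle_fold_target Fold count for the wrinkling inversion.
#' @param wrinkle_r_over_t Radius-to-thickness ratio for the wrinkling
#'   inversion.
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return A list of class `fold_config`.
#' @export
fold_config <- function(stages = c(16.5, 17.5, 18.5), seed = 1, r0 = 400,
                        n_points = 800, boundary_noise_sd = 0,
                        thickness_spacing = 12.5, smoothing_scale = 10,
                        curvature_tolerance = 1e-4,
                        wrinkle_fold_target = 6, wrinkle_r_over_t = 16,
                        out_dir = NULL) {
  cfg <- list(
    stages = stages, seed = as.integer(seed), r0 = r0, n_points = n_points,
    boundary_noise_sd = boundary_noise_sd,
    thickness_spacing = thickness_spacing,
    smoothing_scale = smoothing_scale,
    curvature_tolerance = curvature_tolerance,
    wrinkle_fold_target = wrinkle_fold_target,
    wrinkle_r_over_t = wrinkle_r_over_t,
    out_dir = out_dir,
    version = as.character(utils::packageVersion("cerefold"))
  )
  class(cfg) <- "fold_config"
  cfg
}

#' @rdname fold_config
#' @param path JSON path.
#' @export
write_fold_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname fold_config
#' @export
read_fold_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(fold_config, raw[setdiff(names(raw), "version")])
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' For each requested stage: simulates a section at `epsilon(stage)`,
#' measures it (EGL length, section area, folding index, thickness profile
#' and thickness-oscillation amplitude, measured shape factor), computes the
#' multi-phase model prediction and the semicircular baseline, and tabulates
#' the elastic-wrinkling requirement. All randomness derives from the config
#' seed, so a rerun reproduces the report exactly.
#'
#' @param config A [fold_config()].
#' @return An object of class `fold_report`: list with `config`,
#'   `measurements` (per-stage tibble), `comparison` (shape factor:
#'   semicircle / model / measured per stage) and `wrinkling` (one-row
#'   tibble). If `config$out_dir` is set, CSV tables and a JSON summary are
#'   written there.
#' @examples
#' \donttest{
#' rep <- run_full_analysis(fold_config(stages = 16.5, n_points = 400))
#' rep$comparison
#' }
#' @export
run_full_analysis <- function(config = fold_config()) {
  stopifnot(inherits(config, "fold_config"))
  eps <- epsilon_of_time(config$stages)
  rows <- vector("list", length(config$stages))
  for (i in seq_along(config$stages)) {
    stage <- config$stages[i]
    g <- simulate_section(eps[i], r0 = config$r0, n_points = config$n_points,
                          boundary_noise_sd = config$boundary_noise_sd,
                          seed = config$seed + i)
    rows[[i]] <- tryCatch(
      measure_stage(g, config, stage, eps[i]),
      error = function(e) stop("stage E", stage, " failed in measurement: ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  meas <- dplyr::bind_rows(rows)
  model_sf <- vapply(eps, function(e)
    shape_factor(model_shape(params_at_epsilon(e, r0 = config$r0),
                             domain = "half")), numeric(1))
  comparison <- tibble::tibble(
    stage = config$stages,
    epsilon = eps,
    shape_factor_semicircle = sqrt(2 * pi),
    shape_factor_model = model_sf,
    shape_factor_measured = meas$shape_factor
  )
  wr <- tibble::tibble(
    fold_target = config$wrinkle_fold_target,
    r_over_t = config$wrinkle_r_over_t,
    required_ratio = required_stiffness_ratio(config$wrinkle_fold_target,
                                              config$wrinkle_r_over_t)
  )
  report <- structure(list(config = config, measurements = meas,
                           comparison = comparison, wrinkling = wr),
                      class = "fold_report")
  if (!is.null(config$out_dir)) write_fold_report(report, config$out_dir)
  report
}

measure_stage <- function(g, config, stage, eps) {
  m_outer <- contour_metrics(g$outer, smoothing_scale = config$smoothing_scale)
  # section area: outer arc closed by the base segment
  sect <- as_contour(tibble::tibble(x = g$outer$x, y = g$outer$y),
                     closed = TRUE, check_simple = FALSE)
  area <- abs(shoelace_area(sect$x, sect$y))
  prof <- thickness_profile(g$inner, g$outer, spacing = config$thickness_spacing)
  amp_ratio <- (max(prof$thickness) - min(prof$thickness)) / 2 /
    attr(prof, "mean_thickness")
  tibble::tibble(
    stage = stage, epsilon = eps,
    egl_length = m_outer$length,
    section_area = area,
    folding_index = folding_index(g$outer,
                                  smoothing_scale = config$smoothing_scale,
                                  curvature_tolerance = config$curvature_tolerance),
    mean_thickness = attr(prof, "mean_thickness"),
    at_over_t0 = amp_ratio,
    ac_count = length(g$ac_positions),
    shape_factor = shape_factor(g$outer, half_area = area)
  )
}

#' @export
print.fold_report <- function(x, ...) {
  cat("<fold report>\n")
  cat(sprintf("  stages: %s (seed %d)\n",
              paste(x$config$stages, collapse = ", "), x$config$seed))
  cat("  shape factor (semicircle / model / measured):\n")
  for (i in seq_len(nrow(x$comparison))) {
    r <- x$comparison[i, ]
    cat(sprintf("    E%.1f: %.4f / %.4f / %.4f\n", r$stage,
                r$shape_factor_semicircle, r$shape_factor_model,
                r$shape_factor_measured))
  }
  cat(sprintf("  wrinkling requirement: Eo/Ei >= %.1f for %d folds at R/t = %g\n",
              x$wrinkling$required_ratio, x$wrinkling$fold_target,
              x$wrinkling$r_over_t))
  invisible(x)
}

write_fold_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$measurements, file.path(out_dir, "measurements.csv"))
  readr::write_csv(report$comparison, file.path(out_dir, "comparison.csv"))
  readr::write_csv(report$wrinkling, file.path(out_dir, "wrinkling.csv"))
  jsonlite::write_json(
    list(config = unclass(report$config),
         comparison = report$comparison,
         wrinkling = report$wrinkling),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
  invisible(out_dir)
}
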