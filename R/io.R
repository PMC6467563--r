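# File formats: contours as CSV (x_um, y_um), sections as a JSON manifest
# plus contour CSVs, cells as CSV with 0/1 marker columns, fiber images as
# TIFF with a JSON sidecar, ground truth as JSON.

#' Read and write contour CSV files
#'
#' Contours are exchanged as CSV with header `x_um,y_um`, one ordered point
#' per row.
#'
#' @param contour A contour.
#' @param path File path.
#' @param closed Whether the stored contour is closed (not recorded in the
#'   CSV itself).
#' @return `write_contour_csv()` returns `path` invisibly;
#'   `read_contour_csv()` returns a contour.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(is_contour(contour))
  readr::write_csv(tibble::tibble(x_um = contour$x, y_um = contour$y), path)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path, closed = FALSE) {
  d <- readr::read_csv(path, col_types = readr::cols(
    x_um = readr::col_double(), y_um = readr::col_double()))
  as_contour(data.frame(x = d$x_um, y = d$y_um), closed = closed)
}

#' Read and write section manifests
#'
#' A section is stored as a JSON manifest naming the outer and inner contour
#' CSV files (relative to the manifest), the base segment endpoints, the AC
#' arc-length positions and the stage, with the ground truth (if any) as a
#' sidecar `<name>_truth.json`.
#'
#' @param geometry A `section_geometry`.
#' @param path Manifest path (`.json`).
#' @return `write_section()` returns `path` invisibly; `read_section()`
#'   returns a `section_geometry`.
#' @export
write_section <- function(geometry, path) {
  stopifnot(inherits(geometry, "section_geometry"))
  stem <- sub("\\.json$", "", path)
  outer_f <- paste0(basename(stem), "_outer.csv")
  inner_f <- paste0(basename(stem), "_inner.csv")
  write_contour_csv(geometry$outer, file.path(dirname(path), outer_f))
  write_contour_csv(geometry$inner, file.path(dirname(path), inner_f))
  manifest <- list(
    outer = outer_f, inner = inner_f,
    base = list(x_um = geometry$base$x, y_um = geometry$base$y),
    ac_positions_um = geometry$ac_positions,
    ac_positions_outer_um = geometry$ac_positions_outer,
    stage = geometry$stage
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(geometry$ground_truth))
    write_ground_truth(geometry$ground_truth, paste0(stem, "_truth.json"))
  invisible(path)
}

#' @rdname write_section
#' @export
read_section <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  stem <- sub("\\.json$", "", path)
  truth_path <- paste0(stem, "_truth.json")
  structure(list(
    outer = read_contour_csv(file.path(dirname(path), m$outer)),
    inner = read_contour_csv(file.path(dirname(path), m$inner)),
    base = tibble::tibble(x = m$base$x_um, y = m$base$y_um),
    ac_positions = as.numeric(m$ac_positions_um),
    ac_positions_outer = as.numeric(m$ac_positions_outer_um),
    stage = m$stage,
    ground_truth = if (file.exists(truth_path)) read_ground_truth(truth_path)
  ), class = "section_geometry")
}

#' Read and write cell tables
#'
#' Cells are exchanged as CSV `x_um,y_um,dapi,edu,p27` with 0/1 markers (a
#' `region` column is preserved when present).
#'
#' @param cells A cell table.
#' @param path File path.
#' @return `write_cells_csv()` returns `path` invisibly; `read_cells_csv()`
#'   a `cell_table` tibble.
#' @export
write_cells_csv <- function(cells, path) {
  d <- tibble::tibble(x_um = cells$x, y_um = cells$y,
                      dapi = as.integer(cells$dapi),
                      edu = as.integer(cells$edu),
                      p27 = as.integer(cells$p27))
  if ("region" %in% names(cells)) d$region <- cells$region
  readr::write_csv(d, path)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols())
  out <- tibble::tibble(x = d$x_um, y = d$y_um,
                        dapi = d$dapi > 0, edu = d$edu > 0, p27 = d$p27 > 0)
  if ("region" %in% names(d)) out$region <- d$region
  class(out) <- c("cell_table", class(out))
  out
}

#' Read and write fiber image tiles
#'
#' The intensity matrix is stored as a 32-bit float TIFF scaled to `[0, 1]`;
#' the scale, pixel size, edge contour, AC position and ground truth go into
#' a JSON sidecar `<name>.json`.
#'
#' @param image A `fiber_image`.
#' @param path TIFF path.
#' @return `write_fiber_image()` returns `path` invisibly;
#'   `read_fiber_image()` a `fiber_image`.
#' @export
write_fiber_image <- function(image, path) {
  stopifnot(inherits(image, "fiber_image"))
  mx <- max(image$intensity)
  tiff::writeTIFF(image$intensity / mx, path, bits.per.sample = 32L)
  sidecar <- list(
    scale = mx, pixel_size_um = image$pixel_size,
    edge = list(x_um = image$edge$x, y_um = image$edge$y),
    ac_position_um = image$ac_position,
    ground_truth = serializable_truth(image$ground_truth)
  )
  jsonlite::write_json(sidecar, paste0(sub("\\.tiff?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fiber_image
#' @export
read_fiber_image <- function(path) {
  m <- tiff::readTIFF(path)
  sc <- jsonlite::read_json(paste0(sub("\\.tiff?$", "", path), ".json"),
                            simplifyVector = TRUE)
  structure(list(
    intensity = m * sc$scale,
    pixel_size = sc$pixel_size_um,
    edge = tibble::tibble(x = sc$edge$x_um, y = sc$edge$y_um),
    ac_position = sc$ac_position_um,
    ground_truth = sc$ground_truth
  ), class = "fiber_image")
}

#' Ground-truth sidecar files
#'
#' Every generator's parameters and derived true values are serialized as
#' JSON next to the dataset so measurements can be validated against them.
#'
#' @param truth Ground-truth list.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(serializable_truth(truth), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

serializable_truth <- function(truth) {
  truth[!vapply(truth, is.null, logical(1))]
}

#' Write a thickness profile as CSV
#'
#' @param profile A [thickness_profile()].
#' @param path File path.
#' @export
write_thickness_profile_csv <- function(profile, path) {
  d <- tibble::tibble(position_um = profile$position,
                      thickness_um = profile$thickness,
                      normalized = profile$normalized)
  readr::write_csv(d, path)
  invisible(path)
}
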