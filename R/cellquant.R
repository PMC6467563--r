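#' Measurement windows around an anchoring center
#'
#' Builds the sliding windows used to score proliferation through an
#' anchoring center: a window of width `window` (and the same depth, measured
#' inward from the outer EGL surface) is centered at the AC, and further
#' windows are centered every `step` micrometres anteriorly and posteriorly
#' out to `extent` on each side — 21 windows at the defaults. Windows whose
#' arc interval would run past a contour end are truncated and flagged.
#'
#' @param contour The outer EGL boundary contour.
#' @param ac_position Arc-length position of the AC along `contour`, um.
#' @param window Window width along the arc, um.
#' @param step Center-to-center spacing, um.
#' @param extent Maximum |offset| from the AC, um (a multiple of `step`).
#' @param depth Inward depth of each window, um (defaults to `window`).
#' @return A tibble of class `region_windows`: one row per window with
#'   `offset` (signed um from the AC), `center` (arc length), `width`,
#'   `depth`, `truncated`, `side` (`anterior`/`center`/`posterior`) and
#'   `polygon` (list column of two-column matrices).
#' @examples
#' g <- simulate_section(0.3, seed = 1)
#' w <- ac_windows(g$outer, g$ac_positions_outer[2])
#' nrow(w)  # 21
#' @export
ac_windows <- function(contour, ac_position, window = 50, step = 25,
                       extent = 250, depth = window) {
  stopifnot(is_contour(contour))
  if (window <= 0 || step <= 0 || depth <= 0)
    stop("window, step and depth must be positive", call. = FALSE)
  if (extent %% step != 0)
    stop("extent must be a multiple of step", call. = FALSE)
  L <- contour_length(contour)
  if (ac_position < 0 || ac_position > L)
    stop("ac_position lies outside the contour", call. = FALSE)
  rc <- resample_contour(contour, spacing = min(1, L / 256))
  s <- cum_arc_length(rc$x, rc$y)[seq_len(nrow(rc))]
  nrm <- inward_normals(rc)
  offsets <- seq(-extent, extent, by = step)
  rows <- lapply(offsets, function(off) {
    ctr <- ac_position + off
    a <- ctr - window / 2; b <- ctr + window / 2
    truncated <- a < 0 || b > L
    a <- max(a, 0); b <- min(b, L)
    if (b - a <= 0) return(NULL)
    sel <- which(s >= a & s <= b)
    if (length(sel) < 2L) return(NULL)
    fwd <- cbind(rc$x[sel], rc$y[sel])
    back <- fwd + depth * nrm[sel, , drop = FALSE]
    poly <- rbind(fwd, back[rev(seq_len(nrow(back))), , drop = FALSE])
    tibble::tibble(offset = off, center = ctr, width = b - a, depth = depth,
                   truncated = truncated,
                   side = if (off < 0) "anterior" else if (off > 0) "posterior" else "center",
                   polygon = list(poly))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("region_windows", class(out))
  out
}

# Unit normals of a uniformly resampled contour, oriented toward the side of
# the contour's own centroid (the tissue interior for an outer boundary arc).
inward_normals <- function(rc) {
  x <- rc$x; y <- rc$y
  n <- length(x)
  ip <- c(1L, 1:(n - 1L)); inx <- c(2:n, n)
  tx <- x[inx] - x[ip]; ty <- y[inx] - y[ip]
  tl <- sqrt(tx^2 + ty^2)
  nx <- ty / tl; ny <- -tx / tl
  ctr <- c(mean(x), mean(y))
  vote <- sum(nx * (ctr[1] - x) + ny * (ctr[2] - y))
  if (vote < 0) { nx <- -nx; ny <- -ny }
  cbind(nx, ny)
}

#' Angular AC sector for late-stage sections (experimental)
#'
#' Once an anchoring center is fully formed (around E18.5) the AC region is
#' scored as everything proximal to the section centroid under the midpoint
#' of the AC, rather than by an arc-length window. The published construction
#' is not fully specified in 2D; here it is realized as an angular sector:
#' the polygon spanned from the section centroid out to the outer boundary
#' over `half_angle` radians on either side of the AC midpoint. Treat results
#' as experimental and check them against the arc-length windows.
#'
#' @param geometry A `section_geometry`.
#' @param ac_index Which AC (index into `geometry$ac_positions_outer`).
#' @param half_angle Angular half-width of the sector, radians.
#' @return A two-column matrix polygon usable with [proliferation_rate()].
#' @export
ac_sector_polygon <- function(geometry, ac_index = 1, half_angle = 0.1) {
  stopifnot(inherits(geometry, "section_geometry"))
  outer <- geometry$outer
  band <- egl_band_polygon(geometry)
  ctr <- c(mean(band[, 1]), mean(band[, 2]))
  s <- cum_arc_length(outer$x, outer$y)[seq_len(nrow(outer))]
  s_ac <- geometry$ac_positions_outer[ac_index]
  i_ac <- which.min(abs(s - s_ac))
  ang <- atan2(outer$y - ctr[2], outer$x - ctr[1])
  ang_ac <- ang[i_ac]
  sel <- which(abs(ang - ang_ac) <= half_angle)
  if (length(sel) < 2L) stop("sector too narrow for the contour sampling", call. = FALSE)
  rbind(ctr, cbind(outer$x[sel], outer$y[sel]))
}

#' Proliferation rate (S-phase index) within a window
#'
#' The EGL proliferation rate is the number of EdU+ cells over the number of
#' eligible proliferative cells, `EdU+ / (DAPI+, P27-)`, among cells falling
#' inside the window polygon. An empty denominator yields `NA` (missing), not
#' zero.
#'
#' @param cells A data frame with numeric `x`, `y` and logical `dapi`, `edu`,
#'   `p27` columns (e.g. from [simulate_cells()]).
#' @param window One row of an [ac_windows()] tibble, or a two-column
#'   matrix/data frame polygon.
#' @return Proliferation rate in `[0, 1]`, or `NA` if no eligible cells.
#' @export
proliferation_rate <- function(cells, window) {
  poly <- window_polygon(window)
  stopifnot(all(c("x", "y", "dapi", "edu", "p27") %in% names(cells)))
  inside <- points_in_polygon(cbind(cells$x, cells$y), poly)
  eligible <- inside & cells$dapi & !cells$p27
  if (!any(eligible)) return(NA_real_)
  sum(cells$edu & eligible) / sum(eligible)
}

window_polygon <- function(window) {
  if (is.matrix(window) || (is.data.frame(window) && !"polygon" %in% names(window)))
    return(as.matrix(window))
  if (is.data.frame(window) && nrow(window) == 1L) return(window$polygon[[1]])
  stop("window must be a polygon or a single window row", call. = FALSE)
}

#' Proliferation rates for a set of AC windows
#'
#' @param cells Cell table (see [proliferation_rate()]).
#' @param windows An [ac_windows()] tibble.
#' @return The windows tibble with `n_eligible`, `n_edu` and `rate` columns
#'   (polygons dropped).
#' @export
proliferation_by_window <- function(cells, windows) {
  res <- purrr::map(windows$polygon, function(poly) {
    inside <- points_in_polygon(cbind(cells$x, cells$y), poly)
    eligible <- inside & cells$dapi & !cells$p27
    tibble::tibble(n_eligible = sum(eligible), n_edu = sum(cells$edu & eligible))
  })
  out <- dplyr::bind_cols(dplyr::select(windows, -"polygon"), dplyr::bind_rows(res))
  dplyr::mutate(out, rate = ifelse(.data$n_eligible > 0,
                                   .data$n_edu / .data$n_eligible, NA_real_))
}
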