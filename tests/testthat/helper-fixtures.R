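# Fixture builders shared across tests; everything is generated in code.

circle_contour <- function(radius = 1, n = 2000, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  as_contour(data.frame(x = center[1] + radius * cos(th),
                        y = center[2] + radius * sin(th)),
             closed = TRUE, check_simple = FALSE)
}

ellipse_contour <- function(a = 2, b = 1, n = 2000) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  as_contour(data.frame(x = a * cos(th), y = b * sin(th)),
             closed = TRUE, check_simple = FALSE)
}

polar_contour <- function(rfun, n = 4000, closed = TRUE) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- rfun(th)
  as_contour(data.frame(x = r * cos(th), y = r * sin(th)),
             closed = closed, check_simple = FALSE)
}

semicircle_arc <- function(radius = 1, n = 800) {
  th <- seq(0, pi, length.out = n)
  as_contour(data.frame(x = radius * cos(th), y = radius * sin(th)))
}

# Independent fine-quadrature perimeter of an ellipse (arc-length integral).
ellipse_perimeter_quadrature <- function(a, b, n = 2e5) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  f <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
  h <- th[2] - th[1]
  h * (sum(f) - (f[1] + f[length(f)]) / 2)
}

# Brute-force convex arc fraction of a polar curve r(theta) from the analytic
# polar curvature kappa = (r^2 + 2 r'^2 - r r'') / (r^2 + r'^2)^(3/2),
# integrated on a fine grid, independent of the contour pipeline.
polar_convex_fraction <- function(rfun, drfun, ddrfun, n = 2e5) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- rfun(th); dr <- drfun(th); ddr <- ddrfun(th)
  kappa <- (r^2 + 2 * dr^2 - r * ddr) / (r^2 + dr^2)^1.5
  ds <- sqrt(r^2 + dr^2) * (2 * pi / n)
  sum(ds[kappa >= 0]) / sum(ds)
}

# Hand-built thickness profile object for ratio tests.
make_profile <- function(position, thickness) {
  out <- tibble::tibble(position = position, thickness = thickness,
                        normalized = thickness / mean(thickness))
  class(out) <- c("thickness_profile", class(out))
  attr(out, "mean_thickness") <- mean(thickness)
  attr(out, "dropped") <- 0L
  out
}
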