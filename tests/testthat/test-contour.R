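test_that("circle metrics match the closed forms", {
  circ <- circle_contour(1, 2000)
  m <- contour_metrics(circ)
  expect_equal(m$length, 2 * pi, tolerance = 1e-5)
  expect_equal(m$area, pi, tolerance = 1e-5)
  expect_true(all(abs(m$curvature$curvature - 1) < 1e-3))
})

test_that("open arcs give arc length and refuse area", {
  arc <- semicircle_arc(200, 1200)
  m <- contour_metrics(arc)
  expect_equal(m$length, pi * 200, tolerance = 1e-5)
  expect_true(is.na(m$area))
  expect_error(contour_metrics(arc, area = TRUE), "open contour")
})

test_that("ellipse area is exact and perimeter matches a quadrature oracle", {
  ell <- ellipse_contour(2, 1, 4000)
  m <- contour_metrics(ell)
  expect_equal(m$area, 2 * pi, tolerance = 1e-5)
  oracle <- ellipse_perimeter_quadrature(2, 1)
  expect_equal(m$length, oracle, tolerance = 1e-5)
})

test_that("arc length and area converge at roughly second order", {
  errs <- vapply(c(250, 500, 1000), function(n) {
    m <- contour_metrics(circle_contour(1, n))
    abs(m$length - 2 * pi)
  }, numeric(1))
  # doubling the sampling should cut the error by about 4x
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("contour validation enforces the invariants", {
  expect_error(as_contour(data.frame(x = c(0, 1), y = c(0, 0))), "3 points")
  expect_error(as_contour(data.frame(x = c(0, 0, 1), y = c(0, 0, 1))),
               "duplicate")
  expect_error(contour_metrics(as_contour(
    data.frame(x = c(0, 1, 2, 3), y = c(0, 1, 2, 3) * 2))), "degenerate")
  bow <- data.frame(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  expect_error(as_contour(bow, closed = TRUE), "self-intersecting")
  # clockwise input is reoriented counterclockwise
  cw <- as_contour(data.frame(x = cos(-seq(0, 2, length.out = 50)),
                              y = sin(-seq(0, 2, length.out = 50))))
  expect_true(is_contour(cw))
})

test_that("folding index is zero for convex contours and positive with concavities", {
  expect_equal(folding_index(circle_contour(1, 1500), smoothing_scale = 0.01), 0)
  expect_equal(folding_index(ellipse_contour(2, 1, 1500), smoothing_scale = 0.01), 0)
  # degenerate amplitude-zero wave is a circle
  expect_equal(folding_index(polar_contour(function(th) rep(1, length(th))),
                             smoothing_scale = 0.01), 0)
  wavy <- polar_contour(function(th) 1 + 0.2 * sin(6 * th))
  expect_gt(folding_index(wavy, smoothing_scale = 0.005,
                          curvature_tolerance = 1e-6), 0)
})

test_that("folding index matches brute-force curvature-sign integration", {
  rfun <- function(th) 1 + 0.2 * sin(6 * th)
  oracle <- polar_convex_fraction(
    rfun,
    function(th) 1.2 * cos(6 * th),
    function(th) -7.2 * sin(6 * th)
  )
  expected <- 100 * (1 - oracle)
  got <- folding_index(polar_contour(rfun, n = 8000),
                       smoothing_scale = 0.002, curvature_tolerance = 1e-8)
  expect_equal(got, expected, tolerance = 0.02)
})
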