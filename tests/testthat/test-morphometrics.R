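test_that("shape factor of a semicircle is sqrt(2*pi) at any radius", {
  for (r in c(1, 200)) {
    arc <- semicircle_arc(r, 2000)
    expect_equal(shape_factor(arc, half_area = pi * r^2 / 2), sqrt(2 * pi),
                 tolerance = 1e-5)
  }
  expect_error(shape_factor(semicircle_arc(1), half_area = -1), "positive")
})

test_that("model shape factor grows with folding and is resolution-stable", {
  s0 <- model_shape(params_from_epsilon(1e-6), domain = "half")
  expect_equal(shape_factor(s0), sqrt(2 * pi), tolerance = 1e-4)
  s9 <- model_shape(params_from_epsilon(0.9), n_theta = 720, domain = "half")
  sf9 <- shape_factor(s9)
  expect_gt(sf9, sqrt(2 * pi))
  # doubled-resolution polygon discretization agrees
  sf9_hi <- shape_factor(model_shape(params_from_epsilon(0.9),
                                     n_theta = 1440, domain = "half"))
  expect_equal(sf9, sf9_hi, tolerance = 1e-4)
})

test_that("semicircular reference satisfies L^2 = 2*pi*A exactly", {
  expect_equal(reference_expansion(pi / 2), pi)
  a <- c(10, 1e4, 2.5e5)
  expect_equal(reference_expansion(a)^2, 2 * pi * a)
})

test_that("columnar reference follows the exposed-perimeter conventions", {
  expect_equal(reference_expansion(1e4, "column", column_width = 100), 300)
  expect_equal(reference_expansion(1e4, "column", column_width = 100,
                                   column_convention = "distal"), 100)
  expect_error(reference_expansion(1e4, "column"), "column_width")
  expect_error(reference_expansion(-1), "positive")
})

test_that("sphericity matches analytic values for voxelized bodies", {
  sph <- simulate_ellipsoid_mask(c(20, 20, 20))
  expect_equal(sphericity(sph$mask, sph$voxel_size), 1, tolerance = 0.02)
  pro <- simulate_ellipsoid_mask(c(40, 20, 20))
  expect_equal(sphericity(pro$mask, pro$voxel_size),
               pro$ground_truth$sphericity, tolerance = 0.02)
  # analytic prolate 2:1:1 value ~ 0.929
  expect_equal(pro$ground_truth$sphericity, 0.9287, tolerance = 1e-3)
  expect_error(sphericity(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("sphericity stays below 1 + tolerance and decreases with elongation", {
  vals <- vapply(c(1, 1.5, 2, 3), function(ar) {
    m <- simulate_ellipsoid_mask(c(20 * ar, 20, 20))
    sphericity(m$mask, m$voxel_size)
  }, numeric(1))
  expect_true(all(vals <= 1.02))
  expect_true(all(diff(vals) < 0))
})

test_that("bulk modulus is the impedance-speed product with unit handling", {
  k <- bulk_modulus_from_acoustics(1.5, 1500)
  expect_equal(k$bulk_modulus_gpa, 2.25)
  expect_equal(bulk_modulus_from_acoustics(1.5, 1000)$density_kg_m3, 1500)
  expect_equal(bulk_modulus_from_acoustics(3, 1500)$bulk_modulus_gpa,
               2 * k$bulk_modulus_gpa)
  expect_error(bulk_modulus_from_acoustics(-1, 10), "positive")
})
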