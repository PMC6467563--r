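test_that("generators are pure functions of (params, seed)", {
  g1 <- simulate_section(0.3, boundary_noise_sd = 1, seed = 10)
  g2 <- simulate_section(0.3, boundary_noise_sd = 1, seed = 10)
  expect_equal(g1$outer, g2$outer)
  expect_equal(g1$ac_positions, g2$ac_positions)
  g3 <- simulate_section(0.3, boundary_noise_sd = 1, seed = 11)
  expect_false(isTRUE(all.equal(g1$outer, g3$outer)))

  c1 <- simulate_cells(g1, seed = 3)
  c2 <- simulate_cells(g1, seed = 3)
  expect_equal(c1, c2, ignore_attr = TRUE)

  i1 <- simulate_fiber_image(g1, seed = 4)
  i2 <- simulate_fiber_image(g1, seed = 4)
  expect_equal(i1$intensity, i2$intensity)

  s1 <- simulate_expansion_series("differential", seed = 5)
  s2 <- simulate_expansion_series("differential", seed = 5)
  expect_equal(s1, s2, ignore_attr = TRUE)

  # generators do not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_section(0.3, boundary_noise_sd = 1, seed = 1))
  expect_equal(runif(1), before)
})

test_that("epsilon = 0 gives a clean semicircular annulus", {
  g <- simulate_section(0, seed = 1)
  p <- thickness_profile(g$inner, g$outer)
  expect_equal(diff(range(p$thickness)), 0, tolerance = 1e-3)
  expect_equal(attr(p, "mean_thickness"), 400 / 16, tolerance = 1e-3)
  expect_length(g$ac_positions, 0)
})

test_that("noise-free eps = 0.3 sections carry their ground truth", {
  g <- simulate_section(0.3, seed = 1)
  expect_equal(g$ground_truth$at_over_t0, 0.5)
  expect_equal(g$ground_truth$fold_count, 3L)
  expect_length(g$ac_positions, 3)
  # AC positions sit at thickness maxima: theta = pi/6, pi/2, 5*pi/6
  expect_equal(g$ground_truth$ac_theta, c(pi / 6, pi / 2, 5 * pi / 6),
               tolerance = 5e-3)
})

test_that("excessive boundary noise errors after three attempts", {
  expect_error(
    suppressWarnings(simulate_section(0.3, boundary_noise_sd = 100, seed = 1)),
    "3 regeneration attempts")
})

test_that("expansion series modes place stages on the stated curves", {
  semi <- simulate_expansion_series("semicircle")
  expect_equal(semi$egl_length, sqrt(2 * pi * semi$core_area))
  col <- simulate_expansion_series("column", column_width = 100)
  expect_equal(col$egl_length, 2 * col$core_area / 100 + 100)
  dif <- simulate_expansion_series("differential",
                                   stages = c(16.5, 17.5, 18.5, 19.5, 20.5),
                                   switch_stage = 18.5)
  dev <- dif$egl_length - sqrt(2 * pi * dif$core_area)
  expect_equal(dev[1:2], c(0, 0))
  expect_true(all(dev[3:5] > 0))
  expect_error(simulate_expansion_series(stages = 16.5), "2 strictly increasing")
})

test_that("ellipsoid masks match analytic volume and sphericity", {
  m <- simulate_ellipsoid_mask(c(25, 25, 25))
  vol <- sum(m$mask) * m$voxel_size^3
  expect_equal(vol, m$ground_truth$volume, tolerance = 0.01)
  expect_equal(m$ground_truth$sphericity, 1)
  expect_error(simulate_ellipsoid_mask(c(1, 20, 20)), "resolution")
})
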