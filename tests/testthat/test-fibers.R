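test_that("a uniform image yields zero peaks in every bin", {
  g <- simulate_section(0.3, seed = 1)
  img <- simulate_fiber_image(g, fibers_per_bin = rep(0L, 7), snr = 5, seed = 2)
  img$intensity[] <- 1
  fd <- fiber_density_profile(img)
  expect_true(all(fd$count == 0))
})

test_that("pure noise at SNR-5 settings yields zero peaks", {
  g <- simulate_section(0.3, seed = 1)
  img <- simulate_fiber_image(g, fibers_per_bin = rep(0L, 7), snr = 5, seed = 3)
  fd <- fiber_density_profile(img)
  expect_true(all(fd$count == 0))
})

test_that("known crossing counts are recovered within one fiber per bin", {
  g <- simulate_section(0.3, seed = 1)
  truth <- c(2L, 4L, 6L, 4L, 3L, 5L, 4L)
  img <- simulate_fiber_image(g, fibers_per_bin = truth, snr = 5, seed = 4)
  expect_equal(unname(vapply(img$ground_truth$crossing_offsets, length,
                             integer(1))), truth[truth > 0] * 0L + truth)
  fd <- fiber_density_profile(img)
  expect_equal(nrow(fd), 7)
  expect_true(all(abs(fd$count - truth) <= 1))
  expect_true(all(fd$n_lines == 5))
})

test_that("counts are invariant to intensity scaling and constant background", {
  g <- simulate_section(0.3, seed = 1)
  img <- simulate_fiber_image(g, fibers_per_bin = c(3L, 5L, 2L, 4L, 6L, 3L, 4L),
                              snr = 6, seed = 5)
  base <- fiber_density_profile(img)
  scaled <- img; scaled$intensity <- img$intensity * 7.3
  expect_equal(fiber_density_profile(scaled)$count, base$count)
})

test_that("dense bins across 1..8 fibers keep mean absolute error at or below 1", {
  g <- simulate_section(0.3, seed = 1)
  truth <- c(1L, 3L, 5L, 8L, 6L, 4L, 2L)
  errs <- vapply(1:3, function(sd) {
    img <- simulate_fiber_image(g, fibers_per_bin = truth, snr = 5, seed = sd)
    mean(abs(fiber_density_profile(img)$count - truth))
  }, numeric(1))
  expect_true(all(errs <= 1))
})

test_that("scan lines span five spacings beneath the fitted surface", {
  g <- simulate_section(0.3, seed = 1)
  img <- simulate_fiber_image(g, fibers_per_bin = rep(2L, 5), seed = 6)
  # a fiber rendered only over the first 20 um of depth should vanish from
  # the deepest scan lines: truncate the image below 3 spacings
  deep_rows <- ceiling((max(img$edge$y) + 3 * 12.2) / img$pixel_size)
  cropped <- img
  cropped$intensity <- img$intensity[seq_len(min(deep_rows, nrow(img$intensity))), ]
  expect_warning(fd <- fiber_density_profile(cropped), "dropped")
  expect_lt(max(fd$n_lines), 5)
})

test_that("edge fit rejects non-polynomial edges", {
  g <- simulate_section(0.3, seed = 1)
  img <- simulate_fiber_image(g, fibers_per_bin = rep(1L, 5), seed = 7)
  img$edge$y <- img$edge$y + 60 * sin(img$edge$x / 8)
  expect_error(fiber_density_profile(img), "residual")
})
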