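test_that("annulus thickness is the radius difference, independent of spacing", {
  inner <- circle_contour(200, 1500)
  outer <- circle_contour(215, 1500)
  for (sp in c(5, 12.5, 40)) {
    p <- thickness_profile(inner, outer, spacing = sp)
    expect_equal(p$thickness, rep(15, nrow(p)), tolerance = 1e-3)
    expect_equal(p$normalized, rep(1, nrow(p)), tolerance = 1e-6)
  }
})

test_that("sample count follows the 12.5 um sampling rule", {
  # inner boundary of length 500 um at 12.5 um spacing -> 40 samples
  r <- 500 / (2 * pi)
  p <- thickness_profile(circle_contour(r, 2000), circle_contour(r + 10, 2000))
  expect_equal(nrow(p), 40)
  expect_true(all(diff(p$position) > 0))
  expect_equal(mean(p$normalized), 1, tolerance = 1e-9)
})

test_that("profile errors on bad input", {
  inner <- circle_contour(200, 500)
  expect_error(thickness_profile(inner, inner), "touch|intersect")
  expect_error(thickness_profile(inner, circle_contour(215, 500), spacing = 1e5),
               "spacing")
})

test_that("model-generated boundaries recover the thickness oscillation", {
  g <- simulate_section(0.3, seed = 11)
  p <- thickness_profile(g$inner, g$outer)
  amp <- (max(p$thickness) - min(p$thickness)) / 2 / attr(p, "mean_thickness")
  expect_equal(amp, g$ground_truth$at_over_t0, tolerance = 0.02)
})

test_that("AC thickness ratio behaves on constant and structured profiles", {
  const <- make_profile(seq(0, 1000, by = 12.5), rep(20, 81))
  expect_equal(ac_thickness_ratio(const, 500), 1)

  pos <- seq(0, 1000, by = 5)
  sine <- make_profile(pos, 1 + 0.5 * sin(2 * pi * (pos - 500) / 400 + pi / 2))
  # narrow window at the crest: direct averaging oracle over the same windows
  r <- ac_thickness_ratio(sine, 500, ac_halfwidth = 10, flank_extent = 200)
  off <- abs(pos - 500)
  oracle <- mean(sine$thickness[off <= 10]) /
    mean(sine$thickness[off > 10 & off <= 200])
  expect_equal(r, oracle)
  expect_gt(r, 1.4)
  # at a trough the ratio drops below 1
  trough <- make_profile(pos, 1 + 0.5 * sin(2 * pi * (pos - 500) / 400 - pi / 2))
  expect_lt(ac_thickness_ratio(trough, 500, ac_halfwidth = 10,
                               flank_extent = 200), 1)
  expect_error(ac_thickness_ratio(const, 500, ac_halfwidth = 25,
                                  flank_extent = 25), "flank")
})
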