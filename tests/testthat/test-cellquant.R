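test_that("default AC windows: 21 windows overlapping by half their width", {
  g <- simulate_section(0.3, seed = 2)
  w <- ac_windows(g$outer, g$ac_positions_outer[2])
  expect_equal(nrow(w), 21)
  expect_equal(w$offset, seq(-250, 250, by = 25))
  expect_true(all(!w$truncated))
  # adjacent windows share 25 um of arc
  expect_equal(w$center[2] - w$center[1], 25)
  expect_equal(w$width[1], 50)
  # extent = 0 -> single window
  expect_equal(nrow(ac_windows(g$outer, g$ac_positions_outer[2], extent = 0)), 1)
  expect_error(ac_windows(g$outer, g$ac_positions_outer[2], extent = 30), "multiple")
})

test_that("windows running past the contour ends are truncated and flagged", {
  g <- simulate_section(0.3, seed = 2)
  w <- ac_windows(g$outer, ac_position = 30)
  expect_true(any(w$truncated))
  expect_true(all(w$width[!w$truncated] == 50))
})

test_that("proliferation rate implements EdU+/(DAPI+, P27-)", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  cells <- tibble::tibble(
    x = runif(100, 1, 9), y = runif(100, 1, 9),
    dapi = TRUE,
    p27 = rep(c(TRUE, FALSE), c(50, 50)),
    edu = rep(c(FALSE, TRUE, FALSE), c(50, 20, 30))
  )
  # 20 EdU+ all P27-, denominator 50 -> 0.40
  expect_equal(proliferation_rate(cells, sq), 0.4)
  # duplication leaves the rate unchanged
  expect_equal(proliferation_rate(dplyr::bind_rows(cells, cells), sq), 0.4)
  # cells outside the polygon are ignored
  far <- dplyr::mutate(cells, x = x + 100)
  expect_true(is.na(proliferation_rate(far, sq)))
})

test_that("simulated cells recover the generating EdU rate", {
  g <- simulate_section(0.3, seed = 3)
  cells <- simulate_cells(g, density = 30, edu_rate = 0.35, p27_rate = 0.3,
                          seed = 4)
  # all cells lie inside the EGL band
  band <- cerefold:::egl_band_polygon(g)
  expect_true(all(cerefold:::points_in_polygon(cbind(cells$x, cells$y), band)))
  # whole-band estimate within the 95% binomial interval of the true rate
  elig <- cells$dapi & !cells$p27
  n <- sum(elig)
  expect_gt(n, 500)
  phat <- sum(cells$edu[elig]) / n
  expect_lt(abs(phat - 0.35), 1.96 * sqrt(0.35 * 0.65 / n))
  # zero rate propagates to every window
  cells0 <- simulate_cells(g, density = 20, edu_rate = 0, seed = 5)
  w <- ac_windows(g$outer, g$ac_positions_outer[2])
  rates <- proliferation_by_window(cells0, w)
  expect_true(all(rates$rate[!is.na(rates$rate)] == 0))
})

test_that("empty denominators are missing, not zero", {
  g <- simulate_section(0.3, seed = 3)
  cells <- simulate_cells(g, density = 20, p27_rate = 1, seed = 6)
  w <- ac_windows(g$outer, g$ac_positions_outer[2])
  rates <- proliferation_by_window(cells, w)
  expect_true(all(is.na(rates$rate)))
})

test_that("the experimental AC sector captures cells near the AC midpoint", {
  g <- simulate_section(0.3, seed = 2)
  cells <- simulate_cells(g, density = 30, seed = 3)
  poly <- ac_sector_polygon(g, ac_index = 2, half_angle = 0.12)
  r <- proliferation_rate(cells, poly)
  expect_true(is.finite(r) && r >= 0 && r <= 1)
  inside <- cerefold:::points_in_polygon(cbind(cells$x, cells$y), poly)
  # sector cells cluster around the AC angle (pi/2 for the middle AC)
  ang <- atan2(cells$y[inside], cells$x[inside])
  expect_true(all(abs(ang - pi / 2) < 0.25))
})

test_that("reflection reverses sides but preserves the rate multiset", {
  g <- simulate_section(0.3, seed = 8)
  cells <- simulate_cells(g, density = 30, seed = 9)
  L <- cerefold:::contour_length(g$outer)
  s_ac <- g$ac_positions_outer[2]
  w <- ac_windows(g$outer, s_ac)
  r1 <- proliferation_by_window(cells, w)$rate

  # traverse the boundary the other way: anterior and posterior swap
  refl <- as_contour(g$outer[rev(seq_len(nrow(g$outer))), c("x", "y")])
  w2 <- ac_windows(refl, L - s_ac)
  r2 <- proliferation_by_window(cells, w2)$rate
  # window at offset +d now covers the region formerly at -d
  expect_equal(r1, rev(r2), tolerance = 1e-12)
})
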