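test_that("epsilon = 0.3 reproduces the E16.5 parameter ratios", {
  p <- params_from_epsilon(0.3)
  expect_equal(p$At / p$t0, 0.5)
  expect_equal(p$r0 / p$t0, 16)
  # the amplitude-to-thickness ratio is epsilon-independent
  for (e in c(0.1, 0.5, 0.9)) {
    pe <- params_from_epsilon(e)
    expect_equal(pe$At / pe$t0, 0.5)
  }
  expect_error(params_from_epsilon(0), "epsilon")
  expect_error(params_from_epsilon(1), "epsilon")
})

test_that("epsilon(T) is linear with the stated calibration", {
  expect_equal(epsilon_of_time(16.5), 0.3)
  expect_equal(epsilon_of_time(15.5), 0)
  expect_equal(epsilon_of_time(18.5), 0.9)
  expect_error(epsilon_of_time(19), "validity bound")
  expect_error(epsilon_of_time(15), "negative")
})

test_that("amplitude ratio follows eps/(1-eps)", {
  expect_equal(amplitude_ratio(0.5), 1)
  expect_equal(amplitude_ratio(0), 0)
  expect_equal(amplitude_ratio(0.3), 3 / 7)
  expect_error(amplitude_ratio(1), "epsilon")
})

test_that("the analytic shape carries the printed structure", {
  p <- params_from_epsilon(0.3, r0 = 1)
  s <- model_shape(p, n_theta = 1440)
  # direct substitution at theta = pi/12 (sin(q*theta) = 1 with q = 6)
  t_peak <- stats::approx(s$theta, s$t, pi / 12)$y
  expect_equal(t_peak, (0.0625 + 0.03125) * p$r0, tolerance = 1e-6)
  # epsilon -> 0 limit: circle of radius r0 with uniform thickness t0
  s0 <- model_shape(params_from_epsilon(1e-9))
  expect_equal(s0$r, rep(1, nrow(s0)), tolerance = 1e-6)
  expect_equal(diff(range(s0$t)), 0, tolerance = 1e-9)
  # sampled amplitude ratio equals eps/(1-eps)
  for (e in c(0.1, 0.3, 0.7)) {
    se <- model_shape(params_from_epsilon(e))
    ar <- (max(se$r) - min(se$r)) / (max(se$t) - min(se$t))
    expect_equal(ar, amplitude_ratio(e), tolerance = 1e-6)
  }
})

test_that("thickness and radius oscillate exactly out of phase", {
  for (e in seq(0.05, 0.95, by = 0.15)) {
    s <- model_shape(params_from_epsilon(e))
    expect_lt(abs(stats::cor(s$t, s$r) + 1), 1e-6)
  }
})

test_that("fold counts: q on the circle, q/2 on the half domain", {
  p <- params_from_epsilon(0.3)
  expect_identical(fold_count_model(p), 6L)
  expect_identical(fold_count_model(p, domain = "half"), 3L)
  # robust to grids placing crests exactly between samples
  expect_identical(fold_count_model(model_shape(p, n_theta = 721)), 6L)
  # printed closed-form relation: algebraic inversion gives n = 6
  expect_equal(fold_count_formula(36 * 0.7 / 1.06, 0.06, 0.3, "printed"), 6)
  # derived variant at the same wavenumber uses beta_for_q
  b <- beta_for_q(p, "derived")
  expect_equal(fold_count_formula(p$k_t / b, p$mu / p$k_t, 0.3, "derived"), 6,
               tolerance = 1e-12)
})

test_that("energy functional matches closed-form single-mode integrals", {
  n <- 256
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  k_r <- 1; k_t <- 5; beta <- 0.2; r0 <- 1; t0 <- 0.0625
  expect_equal(energy_functional(rep(r0, n), rep(t0, n), k_r, k_t, beta, r0, t0), 0)
  # r-only perturbation reduces to the k_r quadrature
  r <- r0 + 0.1 * cos(3 * th)
  expect_equal(energy_functional(r, rep(t0, n), k_r, k_t, 0, r0, t0),
               k_r * sum((r - r0)^2) * 2 * pi / n)
  # t = t0 + a sin(q theta), r = r0 -> E = pi a^2 (beta q^2 - k_t)
  a <- 0.03; q <- 6
  t <- t0 + a * sin(q * th)
  expect_equal(energy_functional(rep(r0, n), t, k_r, k_t, beta, r0, t0),
               pi * a^2 * (beta * q^2 - k_t), tolerance = 1e-10)
  # finite differences agree to discretization error
  expect_equal(energy_functional(rep(r0, n), t, k_r, k_t, beta, r0, t0, deriv = "fd"),
               pi * a^2 * (beta * q^2 - k_t), tolerance = 1e-2)
  expect_error(energy_functional(1:4 / 4, 1:5 / 5, 1, 1, 1, 1, 1), "grids")
})

test_that("core area functional matches circle and perturbation identities", {
  n <- 512
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rho <- 0.9375
  expect_equal(core_area(rep(1, n), rep(1 - rho, n)), pi * rho^2)
  s <- model_shape(params_from_epsilon(0.3), n_theta = n)
  expect_equal(core_area(s$r, s$t), attr(s, "A0"), tolerance = 1e-9)
  # zero-mean oscillation of amplitude a on (r - t) adds pi a^2 / 2
  a <- 0.05
  expect_equal(core_area(rep(1, n) + a * sin(4 * th), rep(1 - rho, n)),
               pi * rho^2 + pi * a^2 / 2, tolerance = 1e-12)
})

test_that("the analytic shape satisfies the Euler-Lagrange equations", {
  # the radial equation holds in full; the thickness equation holds in its
  # oscillatory part (the mean thickness is pinned at t0 by the growth
  # convention that fixes C1, not by stationarity, whose mean direction is
  # unstable for k_t > k_r)
  for (e in c(0.1, 0.3, 0.5, 0.8)) {
    p <- params_from_epsilon(e)
    beta <- beta_for_q(p, "derived")
    s <- model_shape(p, n_theta = 1024)
    tpp <- cerefold:::spectral_deriv(cerefold:::spectral_deriv(s$t))
    gap <- s$r - s$t
    res_t <- beta * tpp + p$k_t * (s$t - mean(s$t)) - p$mu * (gap - mean(gap))
    res_r <- p$k_r * (s$r - p$r0) - p$mu * gap
    scale_t <- max(abs(p$k_t * (s$t - mean(s$t))))
    scale_r <- max(abs(p$mu * gap))
    expect_lt(max(abs(res_t)) / scale_t, 1e-8)
    expect_lt(max(abs(res_r)) / scale_r, 1e-8)
  }
})

test_that("scaling r0 scales lengths and areas but not shape", {
  s1 <- model_shape(params_from_epsilon(0.3, r0 = 1), domain = "half")
  s2 <- model_shape(params_from_epsilon(0.3, r0 = 2), domain = "half")
  expect_equal(s2$r, 2 * s1$r)
  expect_equal(s2$t, 2 * s1$t)
  expect_equal(attr(s2, "A0"), 4 * attr(s1, "A0"))
  expect_equal(shape_factor(s2), shape_factor(s1), tolerance = 1e-12)
  expect_identical(fold_count_model(s2), fold_count_model(s1))
})

test_that("stage series composes time map, parameters, shape and shape factor", {
  ser <- predict_stage_series(c(16.5, 17.5, 18.5))
  expect_equal(ser$epsilon, c(0.3, 0.6, 0.9))
  expect_true(all(diff(ser$shape_factor) > 0))
  ser0 <- predict_stage_series(15.5)
  expect_equal(ser0$shape_factor, sqrt(2 * pi), tolerance = 1e-4)
  expect_error(predict_stage_series(19), "validity")
})

test_that("invalid shapes are rejected", {
  expect_error(model_shape(params_from_epsilon(0.3), n_theta = 20), "n_theta")
  # thickness amplitude exceeding the mean makes t go negative
  bad <- model_params(epsilon = 0.3, c = 0.2, at_over_r0 = 0.2,
                      t0_over_r0 = 0.0625)
  expect_error(model_shape(bad), "non-positive")
})
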