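test_that("plateau trimming reproduces the stopping rule", {
  s <- decay_series(0:5, c(10, 9, 8, 8.0001, 8.0000, 8.0001), time_unit = "min")
  expect_equal(nrow(trim_at_plateau(s, tolerance = 0.001)), 4)
  # strictly decreasing record: no plateau, returned unchanged
  dec <- decay_series(0:4, c(10, 9, 8, 7, 6), time_unit = "min")
  expect_identical(trim_at_plateau(dec, 0.001)$value, dec$value)
  # immediate plateau keeps the 3-point minimum a fit needs
  const <- decay_series(0:4, rep(5, 5), time_unit = "min")
  expect_equal(nrow(trim_at_plateau(const, 0.001)), 3)
  expect_error(trim_at_plateau(decay_series(0:1, c(2, 1)), 0.001),
               class = "relkin_insufficient_data")
})

test_that("normalization maps weights to a remaining fraction starting at 1", {
  s <- decay_series(0:2, c(6.0, 5.5, 5.0), time_unit = "min")
  n <- normalize_release(s, plateau_mass = 5.0)
  expect_equal(n$value, c(1, 0.5, 0))
  expect_equal(attr(n, "M0_g"), 1.0)
  # constant weights stay at 1
  cs <- decay_series(0:3, rep(6, 4), time_unit = "min")
  expect_equal(normalize_release(cs, 2)$value, rep(1, 4))
  # plateau 0 recovers the underlying fraction exactly
  f <- exp(-0.01 * (0:5))
  ws <- decay_series(0:5, 0.5 * f, time_unit = "min")
  expect_equal(normalize_release(ws, 0)$value, f, tolerance = 1e-15)
  expect_error(normalize_release(s, 6.5), class = "relkin_invalid_normalization")
})

test_that("first-order release fit recovers the published sample-1 rate exactly", {
  t_min <- seq(0, 300, by = 30)
  s <- decay_series(t_min, exp(-1.46e-3 * t_min), time_unit = "min")
  fit <- fit_first_order_release(s)
  expect_equal(fit$k_per_min, 1.46e-3, tolerance = 1e-6)
  expect_equal(fit$M0, 1, tolerance = 1e-6)
  expect_equal(fit$k_per_s, fit$k_per_min / 60, tolerance = 1e-12)
  # a constant series has no release at all
  const <- decay_series(t_min, rep(0.8, length(t_min)), time_unit = "min")
  expect_equal(fit_first_order_release(const)$k_per_s, 0)
})

test_that("first-order release optimizer beats a dense grid", {
  set.seed(31)
  t_min <- seq(0, 300, by = 30)
  y <- 0.9 * exp(-1.2e-3 * t_min) + rnorm(length(t_min), 0, 0.02)
  s <- decay_series(t_min, pmax(y, 1e-3), time_unit = "min")
  fit <- fit_first_order_release(s)
  ssr_fit <- (1 - fit$r_squared) * sum((s$value - mean(s$value))^2)
  ssr_grid <- grid_ssr_exp(t_min, s$value, P0_range = c(0.7, 1.1),
                           k_range = c(5e-4, 3e-3))
  expect_lte(ssr_fit, ssr_grid + 1e-10)
})

test_that("slab relation D = k L^2 / pi^2 is exact and scales correctly", {
  expect_equal(k_to_diffusivity(pi^2, 1), 1)     # analytic identity
  expect_equal(k_to_diffusivity(0, 0.02), 0)
  # linearity in k, quadratic in L
  k <- 2.4e-5; L <- 0.013
  expect_equal(k_to_diffusivity(2 * k, L), 2 * k_to_diffusivity(k, L))
  expect_equal(k_to_diffusivity(k, 2 * L), 4 * k_to_diffusivity(k, L))
  # per-minute rates convert through 1/60
  expect_equal(k_to_diffusivity(6.69e-4 / 60, 0.020), 4.52e-10,
               tolerance = 1e-3)
  expect_error(k_to_diffusivity(1e-5, -1), class = "relkin_invalid_geometry")
})

test_that("truncated one-term model has its characteristic endpoints", {
  expect_equal(truncated_remaining_fraction(1e-10, 0.005, 0), 4 / pi)
  expect_equal(truncated_remaining_fraction(1e-10, 0.005, 1e12), 0,
               tolerance = 1e-12)
  # the published sample-1 oil-content ratio at 150 min
  expect_equal(truncated_remaining_fraction(2.4e-10, 0.005, 9000), 0.540,
               tolerance = 0.01)
})

test_that("Fickian fitter recovers D exactly from its own model", {
  D <- 1e-10; L <- 0.005
  t <- seq(0, 36000, by = 1800)
  s <- decay_series(t, truncated_remaining_fraction(D, L, t), time_unit = "s")
  fit <- fit_fickian_truncated(s, L = L)
  expect_equal(fit$D_eff, D, tolerance = 1e-6)
  expect_equal(fit$amplitude, 4 / pi, tolerance = 1e-6)
  expect_identical(fit$L_used, L)
  # the pinned-amplitude variant is also exact on its own model
  fixed <- fit_fickian_truncated(s, L = L, fix_amplitude = TRUE)
  expect_equal(fixed$D_eff, D, tolerance = 1e-6)
})

test_that("Fickian fitter recovers D within 10% from full-series data", {
  D <- 1e-10; L <- 0.005
  cfg <- sim_config("fickian_full", list(D = D, L = L),
                    n_points = 21, dt = 1800, seed = 4, n_terms = 50)
  s <- simulate_release(cfg)
  fit <- fit_fickian_truncated(s, L = L)
  expect_lt(abs(fit$D_eff - D) / D, 0.10)
})

test_that("Fickian fitter beats a dense (A, D) grid and guards its window", {
  D <- 1.3e-10; L <- 0.005
  t <- seq(0, 36000, by = 1800)
  set.seed(17)
  y <- truncated_remaining_fraction(D, L, t) + rnorm(length(t), 0, 0.01)
  s <- decay_series(t, pmax(y, 1e-4), time_unit = "s")
  fit <- fit_fickian_truncated(s, L = L)
  tau <- fit$D_eff * pi^2 * t / L^2
  w <- tau >= fit$tau_window & s$value > 0
  ssr_fit <- sum((s$value[w] -
                    fit$amplitude * exp(-fit$D_eff * pi^2 * t[w] / L^2))^2)
  ssr_grid <- grid_ssr_fick(t[w], s$value[w], L,
                            A_range = c(0.8, 1.6),
                            D_range = c(0.5e-10, 2.5e-10))
  expect_lte(ssr_fit, ssr_grid + 1e-12)

  expect_error(fit_fickian_truncated(s), class = "relkin_invalid_geometry")
  short <- decay_series(c(0, 1800), c(1.2, 1.0), time_unit = "s")
  expect_error(fit_fickian_truncated(short, L = L),
               class = "relkin_insufficient_data")
})

test_that("compressing the time axis raises the fitted diffusivity", {
  D <- 1e-10; L <- 0.005
  t <- seq(0, 36000, by = 1800)
  y <- fickian_remaining(t, D, L)
  slow <- fit_fickian_truncated(decay_series(t, y, time_unit = "s"), L = L)
  fast <- fit_fickian_truncated(decay_series(t / 2, y, time_unit = "s"), L = L)
  expect_gt(fast$D_eff, slow$D_eff)
  expect_equal(fast$D_eff / slow$D_eff, 2, tolerance = 1e-6)
})

test_that("full release pipeline recovers the simulator's D within 25%", {
  D <- 1e-10; L <- 0.005
  cfg <- sim_config("fickian_full", list(D = D, L = L, M0 = 0.5),
                    n_points = 21, dt = 1800, seed = 6,
                    plateau_mass = 5.0, as_mass = TRUE)
  w <- simulate_release(cfg)
  # pipeline works in minutes, as the balance record would
  w_min <- decay_series(w$time / 60, w$value, sample_id = "sim",
                        condition = "release", time_unit = "min")
  res <- analyze_release(w_min, plateau_mass = 5.0,
                         L_kinetic = L, L_fick = L)
  expect_lt(abs(res$D_from_k - D) / D, 0.25)
  expect_lt(abs(res$D_eff_fick - D) / D, 0.10)
  # the single-exponential proxy splits the difference between the true
  # initial mass and the first mode's amplitude (8/pi^2 of it)
  expect_equal(res$M0_g, 0.5, tolerance = 0.15)
})
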