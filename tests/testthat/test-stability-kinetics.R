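test_that("stability index is the uncapped percent ratio of absorbances", {
  expect_equal(emulsion_stability(145.1, 145.1), 100)
  expect_equal(emulsion_stability(137.845, 145.1), 95)
  expect_equal(emulsion_stability(0, 100), 0)
  expect_equal(emulsion_stability(120, 100), 120)  # day-2 recoveries exceed 100
  expect_error(emulsion_stability(10, 0), class = "relkin_undefined_ratio")
})

test_that("trajectory reconstruction inverts the stability index", {
  s <- reconstruct_trajectory(233, c(72, 48, 36))
  expect_equal(s$time, 0:3)
  expect_equal(s$value, c(233, 167.76, 111.84, 83.88))
  expect_equal(reconstruct_trajectory(100, c(100, 100))$value, c(100, 100, 100))
  # round trip: stability of the reconstruction reproduces the input percents
  expect_equal(emulsion_stability(s$value[-1], s$value[1]), c(72, 48, 36),
               tolerance = 1e-12)
  expect_error(reconstruct_trajectory(233, c(72, -1)),
               class = "relkin_invalid_input")
  expect_error(reconstruct_trajectory(0, c(72)),
               class = "relkin_invalid_input")
})

test_that("zero-order fit is exact on a line and matches the normal equations", {
  exact <- fit_zero_order(decay_series(0:3, c(100, 90, 80, 70)))
  expect_equal(exact$intercept, 100, tolerance = 1e-12)
  expect_equal(exact$rate, 10, tolerance = 1e-12)
  expect_identical(exact$direction, -1L)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  # random 6-point series against the closed-form OLS oracle
  set.seed(11)
  for (i in 1:5) {
    t <- 0:5
    y <- 150 - 20 * t + rnorm(6, 0, 8)
    fit <- fit_zero_order(decay_series(t, y))
    oracle <- ols_oracle(t, y)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$direction * fit$rate, oracle$slope, tolerance = 1e-10)
    expect_equal(sum((y - fit$fitted)^2), oracle$ssr, tolerance = 1e-10)
  }

  expect_error(fit_zero_order(data.frame(time = c(1, 1, 1), value = 1:3)),
               class = "relkin_degenerate_design")
})

test_that("a saturated 2-point zero-order fit has R^2 exactly 1", {
  fit <- fit_zero_order(decay_series(c(0, 1), c(100, 60)))
  expect_identical(fit$r_squared, 1)
})

test_that("OLS respects affine transforms of the response", {
  set.seed(3)
  t <- 0:4
  y <- 200 - 30 * t + rnorm(5, 0, 5)
  base <- fit_zero_order(decay_series(t, y))
  shifted <- fit_zero_order(decay_series(t, y + 40))
  scaled <- fit_zero_order(decay_series(t, 2.5 * y))
  expect_equal(shifted$intercept, base$intercept + 40, tolerance = 1e-10)
  expect_equal(shifted$rate, base$rate, tolerance = 1e-10)
  expect_equal(scaled$intercept, 2.5 * base$intercept, tolerance = 1e-10)
  expect_equal(scaled$rate, 2.5 * base$rate, tolerance = 1e-10)
  expect_equal(shifted$r_squared, base$r_squared, tolerance = 1e-12)
  expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-12)
})

test_that("first-order fit recovers noiseless exponentials across the design range", {
  for (k in c(0.01, 0.1, 0.5, 1, 2)) {
    for (P0 in c(10, 200, 1000)) {
      s <- decay_series(0:3, P0 * exp(-k * 0:3))
      fit <- fit_first_order(s)
      expect_equal(fit$intercept, P0, tolerance = 1e-6)
      expect_equal(fit$rate, k, tolerance = 1e-6)
      expect_identical(fit$direction, -1L)
    }
  }
})

test_that("first-order optimizer beats a dense grid search", {
  set.seed(21)
  t <- 0:3
  y <- 200 * exp(-0.3 * t) + rnorm(4, 0, 8)
  fit <- fit_first_order(decay_series(t, y))
  ssr_fit <- sum((y - fit$fitted)^2)
  ssr_grid <- grid_ssr_exp(t, y, P0_range = c(100, 300), k_range = c(0.05, 1))
  expect_lte(ssr_fit, ssr_grid + 1e-10)
})

test_that("published fits for the all-xanthan sample at 5 degC are reproduced", {
  s <- reconstruct_trajectory(233, c(72, 48, 36))
  z <- fit_zero_order(s)
  expect_equal(z$intercept, 225, tolerance = 0.01)          # printed 225 +/- 4.8
  expect_equal(z$direction * z$rate, -50, tolerance = 0.01) # printed -50 +/- 2.5
  f <- fit_first_order(s)
  expect_lt(abs(f$intercept - 234), 5)                      # printed 234 +/- 5
  expect_lt(abs(f$direction * f$rate - (-0.34)), 0.02)      # printed -0.34 +/- 0.02
})

test_that("noisy parameter recovery on triplicate-mean trajectories stays under 5%", {
  # deep replicate counts keep the sample median's own error well below the
  # margin between the true medians (~4.3% and ~4.6%) and the 5% bound
  err_z <- vapply(1:2000, function(r) {
    s <- simulate_triplicate_mean("zero_order", list(P0 = 200, k = 40),
                                  n_points = 4, dt = 1, noise_sd = 10,
                                  seed = 100 + 3 * r)
    abs(fit_zero_order(s)$rate - 40) / 40
  }, numeric(1))
  expect_lt(median(err_z), 0.05)

  err_f <- vapply(1:4000, function(r) {
    s <- simulate_triplicate_mean("first_order", list(P0 = 200, k = 0.3),
                                  n_points = 4, dt = 1, noise_sd = 10,
                                  seed = 5000 + 3 * r)
    abs(fit_first_order(s)$rate - 0.3) / 0.3
  }, numeric(1))
  expect_lt(median(err_f), 0.05)
})

test_that("average R^2 validates its collection", {
  fits <- lapply(1:3, function(i) fit_zero_order(
    decay_series(0:3, c(100, 90, 81, 70) - i)))
  expect_equal(average_r_squared(fits),
               mean(vapply(fits, `[[`, numeric(1), "r_squared")))
  expect_equal(average_r_squared(c(0.9, 0.9, 0.9)), 0.9)
  expect_error(average_r_squared(numeric(0)), class = "relkin_invalid_input")
  expect_error(average_r_squared(list()), class = "relkin_invalid_input")
  mixed <- c(fits[1], list(fit_first_order(decay_series(0:3, 200 * exp(-0.3 * 0:3)))))
  expect_error(average_r_squared(mixed), class = "relkin_invalid_input")
})

test_that("rate-peak classifier distinguishes peaked, monotone and flat profiles", {
  expect_identical(detect_rate_peak(c("5" = 38, "20" = 55, "35" = 34)), "peaked")
  expect_identical(detect_rate_peak(c("5" = 10, "20" = 20, "35" = 30)), "monotone")
  expect_identical(detect_rate_peak(c("5" = 49, "20" = 49, "35" = 49)), "flat")
  # temperature order, not input order, decides interiority
  expect_identical(detect_rate_peak(c(55, 34, 38), temperatures = c(20, 35, 5)),
                   "peaked")
  expect_error(detect_rate_peak(c("5" = 1, "20" = 2)),
               class = "relkin_insufficient_data")
})

test_that("study kinetics table shows the 20 degC rate peak for intermediate blends", {
  kt <- study_kinetics_table()
  z2 <- kt[kt$order == 0 & kt$sample_id == "S2", ]
  rates <- setNames(abs(z2$slope), z2$temperature_C)
  expect_identical(detect_rate_peak(rates), "peaked")
})
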