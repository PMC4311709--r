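test_that("aggregate_series block-averages on half-open windows", {
  # 24 half-hour points spanning one 12-h window collapse to their mean
  s <- sensor_series(seq(0, 11.5, by = 0.5), rep(0.1, 24), 1:24)
  # only 1 full window -> too short to keep as a series; use 48 points
  s2 <- sensor_series(seq(0, 23.5, by = 0.5), rep(0.1, 48), 1:48)
  a2 <- aggregate_series(s2, 12)
  expect_equal(nrow(a2), 2)
  expect_equal(a2$co2, c(mean(1:24), mean(25:48)))  # 12.5, 36.5
  expect_equal(a2$time_h, c(0, 12))
  # constant series stays constant
  sc <- sensor_series(seq(0, 23.5, by = 0.5), rep(0.2, 48), rep(5, 48))
  expect_equal(aggregate_series(sc, 12)$co2, c(5, 5))
  expect_error(aggregate_series(s2, 0.25), "smaller")
  expect_error(aggregate_series(s2, 5.25), "multiple")
})

test_that("noiseless series generated by the lag equation is recovered exactly", {
  p <- sensor_sim_params(duration_h = 1200, step_h = 12, noise_sd = 0,
                         rain_times_h = c(96, 336, 700), seed = 3)
  gen <- generate_sensor_series(p)
  fit <- fit_pulse_model(gen$series)
  expect_equal(unname(fit$coefficients),
               unname(gen$coefficients), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # predictions equal observations
  pred <- predict(fit, gen$series)
  expect_equal(pred$predicted, pred$observed, tolerance = 1e-6)
})

test_that("OLS stage matches the explicit normal-equations solution", {
  set.seed(21)
  n <- 60
  moist <- 0.1 + 0.05 * stats::runif(n)
  co2 <- 1000 + cumsum(stats::rnorm(n, 0, 20))
  s <- sensor_series(seq(0, by = 12, length.out = n), moist, co2)
  fit <- fit_pulse_model(s, correction = "none")
  X <- cbind(1, co2[-n], moist[-1], moist[-n])
  beta_oracle <- solve(t(X) %*% X, t(X) %*% co2[-1])
  expect_equal(unname(fit$coefficients), drop(beta_oracle),
               tolerance = 1e-8)
  expect_equal(fit$n_obs, n - 1)
})

test_that("AR(1) correction converges and collapses to OLS when rho = 0", {
  p <- sensor_sim_params(duration_h = 2400, step_h = 12, noise_sd = 15,
                         rain_times_h = c(300, 900, 1500),
                         ar_rho = 0, seed = 4)
  s <- generate_sensor_series(p)$series
  fit_ar <- fit_pulse_model(s, correction = "ar1")
  fit_ols <- fit_pulse_model(s, correction = "none")
  expect_true(fit_ar$converged)
  expect_lt(abs(fit_ar$rho), 0.15)
  expect_equal(unname(fit_ar$coefficients), unname(fit_ols$coefficients),
               tolerance = 0.02)
})

test_that("constant moisture reduces the model to an AR(1) in CO2", {
  set.seed(8)
  n <- 80
  co2 <- numeric(n); co2[1] <- 100
  for (t in 2:n) co2[t] <- 50 + 0.7 * co2[t - 1] + stats::rnorm(1, 0, 5)
  s <- sensor_series(seq(0, by = 12, length.out = n), rep(0.1, n), co2)
  fit <- fit_pulse_model(s, correction = "none")
  expect_true(all(c("moisture", "moisture_lag") %in% fit$aliased))
  ar <- stats::lm(co2[-1] ~ co2[-n])
  pred <- predict(fit, s)
  expect_equal(pred$predicted, unname(stats::fitted(ar)), tolerance = 1e-8)
})

test_that("fully constant series is rejected as singular", {
  s <- sensor_series(seq(0, by = 12, length.out = 20), rep(0.1, 20),
                     rep(800, 20))
  expect_error(fit_pulse_model(s), "singular")
})

test_that("moisture-CO2 link carries the predictive signal (permutation null)", {
  worse <- vapply(1:20, function(sd) {
    p <- sensor_sim_params(duration_h = 1800, step_h = 12, noise_sd = 30,
                           rain_times_h = c(300, 900, 1500), seed = sd)
    s <- generate_sensor_series(p)$series
    r2_real <- fit_pulse_model(s, correction = "none")$r_squared
    perm <- with(s, sensor_series(time_h, sample(moisture), co2))
    r2_perm <- fit_pulse_model(perm, correction = "none")$r_squared
    r2_perm < r2_real
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("fit quality is monotone in noise and invariant to time relabeling", {
  r2 <- vapply(c(200, 50, 5), function(ns) {
    mean(vapply(1:10, function(sd) {
      p <- sensor_sim_params(duration_h = 1200, step_h = 12, noise_sd = ns,
                             rain_times_h = c(96, 336, 700), seed = sd)
      fit_pulse_model(generate_sensor_series(p)$series)$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r2) >= 0))
  # affine relabeling of time leaves the fit unchanged
  p <- sensor_sim_params(duration_h = 600, step_h = 12,
                         rain_times_h = c(100, 300, 500), seed = 2)
  s <- generate_sensor_series(p)$series
  s_shift <- sensor_series(s$time_h * 2 + 100, s$moisture, s$co2)
  f1 <- fit_pulse_model(s); f2 <- fit_pulse_model(s_shift)
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$r_squared, f2$r_squared)
})

test_that("HAC correction keeps OLS point estimates with altered errors", {
  p <- sensor_sim_params(duration_h = 1200, step_h = 12, noise_sd = 20,
                         rain_times_h = c(96, 336, 700),
                         ar_rho = 0.5, seed = 9)
  s <- generate_sensor_series(p)$series
  f_hac <- fit_pulse_model(s, correction = "hac")
  f_ols <- fit_pulse_model(s, correction = "none")
  expect_equal(f_hac$coefficients, f_ols$coefficients)
  expect_false(isTRUE(all.equal(f_hac$se, f_ols$se)))
})
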