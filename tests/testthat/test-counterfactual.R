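# Frozen oracle values: KPSS statistics for two fixed series were computed
# with an independent implementation (statsmodels.tsa.stattools.kpss,
# regression = "c") at matching lag truncations and agree to 1e-10.
test_that("KPSS statistic matches the independent oracle on frozen series", {
  set.seed(42)
  x <- rnorm(500)
  y <- cumsum(rnorm(500))
  # default bandwidth trunc(12*(n/100)^0.25) = 17 at n = 500
  expect_equal(kpss_statistic(x), 0.04197673080079264, tolerance = 1e-10)
  expect_equal(kpss_statistic(y), 2.2494277707292625, tolerance = 1e-10)
  # short bandwidth trunc(3*sqrt(n)/13) = 5 frozen from the same oracle
  expect_equal(kpss_statistic(x, lags = 5), 0.036275293466222415,
               tolerance = 1e-10)
  expect_equal(kpss_statistic(y, lags = 5), 6.630706054648154,
               tolerance = 1e-10)
})

test_that("choose_differencing finds the integration order", {
  set.seed(1)
  expect_identical(choose_differencing(rnorm(500)), 0L)
  set.seed(2)
  expect_identical(choose_differencing(cumsum(rnorm(500))), 1L)
  set.seed(3)
  expect_identical(choose_differencing(cumsum(cumsum(rnorm(500)))), 2L)
  expect_identical(choose_differencing(rep(3.5, 100)), 0L)  # constant series
  expect_error(choose_differencing(rnorm(10)), "too short")
})

test_that("white-noise fit recovers mean and ML variance in closed form", {
  set.seed(10)
  y <- rnorm(400, mean = 5, sd = 2)
  s <- fit_arima(y, c(0, 0, 0))
  expect_equal(s$intercept, mean(y), tolerance = 1e-6)
  expect_equal(s$sigma2, mean((y - mean(y))^2), tolerance = 1e-6)
  expect_equal(s$n_obs, 400L)
  k <- 2  # intercept + sigma2
  expect_equal(s$aicc, s$aic + 2 * k * (k + 1) / (400 - k - 1))
})

test_that("AR and MA coefficients are recovered near independent estimators", {
  set.seed(20)
  y <- as.numeric(arima.sim(list(ar = 0.7), 2000))
  s <- fit_arima(y, c(1, 0, 0))
  # oracle: conditional least squares (lagged regression)
  cls <- unname(coef(lm(y[-1] ~ y[-2000]))[2])
  expect_lt(abs(s$ar - 0.7), 0.05)
  expect_lt(abs(s$ar - cls), 0.02)

  set.seed(21)
  y <- as.numeric(arima.sim(list(ma = 0.5), 2000))
  s <- fit_arima(y, c(0, 0, 1))
  # oracle: method-of-moments inversion of the lag-1 autocorrelation
  r1 <- acf(y, lag.max = 1, plot = FALSE)$acf[2]
  mom <- (1 - sqrt(1 - 4 * r1^2)) / (2 * r1)
  expect_lt(abs(s$ma - 0.5), 0.07)
  expect_lt(abs(mom - 0.5), 0.1)  # both routes agree with the truth
})

test_that("fit_arima rejects degenerate or too-short input", {
  expect_error(fit_arima(rep(2, 50), c(1, 0, 0)), "zero-variance")
  expect_error(fit_arima(rnorm(6), c(2, 0, 2)), "too short")
  expect_error(fit_arima(c(rnorm(10), NA, rnorm(10)), c(1, 0, 0)), "missing")
})

test_that("random-walk and mean-model forecasts have their closed forms", {
  set.seed(30)
  y <- cumsum(rnorm(300)) + 50
  s <- fit_arima(y, c(0, 1, 0), include_constant = FALSE)
  f <- forecast_counterfactual(s, 10)
  expect_equal(f$mean, rep(y[300], 10))
  expect_true(all(diff(f$se) > 0))  # widening intervals for d = 1

  set.seed(31)
  y <- rnorm(200, 5)
  s <- fit_arima(y, c(0, 0, 0))
  f <- forecast_counterfactual(s, 6)
  expect_equal(f$mean, rep(s$intercept, 6))
  expect_equal(f$se, rep(sqrt(s$sigma2), 6), tolerance = 1e-8)
})

test_that("AR(1) forecasts follow mu + phi^h (y_T - mu) exactly", {
  set.seed(32)
  y <- as.numeric(arima.sim(list(ar = 0.8), 500)) + 20
  s <- fit_arima(y, c(1, 0, 0))
  f <- forecast_counterfactual(s, 10)
  closed <- s$intercept + s$ar^(1:10) * (y[500] - s$intercept)
  expect_equal(f$mean, closed, tolerance = 1e-10)
  # d = 0: the forecast converges to the unconditional mean
  expect_equal(forecast_counterfactual(s, 200)$mean[200], s$intercept,
               tolerance = 1e-6)
})

test_that("forecast intervals honour level and basic validation", {
  set.seed(33)
  s <- fit_arima(rnorm(100), c(0, 0, 0))
  f95 <- forecast_counterfactual(s, 5, level = 0.95)
  f80 <- forecast_counterfactual(s, 5, level = 0.80)
  expect_true(all(f95$lower <= f95$mean & f95$mean <= f95$upper))
  expect_true(all(f95$upper - f95$lower > f80$upper - f80$lower))
  expect_error(forecast_counterfactual(s, 0), "horizon")
  expect_error(forecast_counterfactual(s, 5, level = 1.2), "level")
})

test_that("forecast-error variance is non-decreasing in horizon", {
  set.seed(34)
  specs <- list(
    fit_arima(as.numeric(arima.sim(list(ar = c(0.5, 0.2)), 400)), c(2, 0, 0)),
    fit_arima(as.numeric(arima.sim(list(ma = 0.6), 400)), c(0, 0, 1)),
    fit_arima(cumsum(as.numeric(arima.sim(list(ar = 0.4), 400))), c(1, 1, 0),
              include_constant = FALSE),
    fit_arima(cumsum(rnorm(400)) + 0.2 * (1:400), c(0, 1, 1)))
  for (s in specs) {
    f <- forecast_counterfactual(s, 30)
    expect_true(all(diff(f$se) > -1e-10))
  }
})

test_that("stepwise selection behaves on simple processes", {
  set.seed(40)
  y <- rnorm(300)
  s <- select_order(y, max_p = 3, max_q = 3)
  expect_lte(s$p + s$q, 2)  # white noise should select a small model
  expect_identical(s$d, 0L)

  set.seed(41)
  y <- as.numeric(arima.sim(list(ar = 0.8), 800))
  s <- select_order(y, max_p = 3, max_q = 3)
  expect_identical(s$d, 0L)
  expect_gt(s$p + s$q, 0)
})

test_that("stepwise AICc is close to the exhaustive minimum (fixed seeds)", {
  for (seed in c(101, 102)) {
    set.seed(seed)
    y <- as.numeric(arima.sim(list(ar = 0.8), 400)) + 3
    sw <- select_order(y, max_p = 3, max_q = 3, d = 0L)
    ex <- select_order(y, max_p = 3, max_q = 3, d = 0L, stepwise = FALSE)
    expect_lte(sw$aicc, ex$aicc + 2)
  }
})

test_that("refitting the selected orders reproduces the AICc", {
  set.seed(50)
  y <- as.numeric(arima.sim(list(ar = 0.7), 500)) + 8
  s <- select_order(y, max_p = 3, max_q = 3)
  refit <- fit_arima(y, c(s$p, s$d, s$q), include_constant = s$include_constant)
  expect_equal(refit$aicc, s$aicc, tolerance = 1e-8)
})
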