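# Forecast metrics, stationarity diagnostics, AR fitting and recovery,
# residual-error correction, and naive prediction intervals.

test_that("forecast metrics follow the signed-error convention", {
  m <- forecast_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(rmse = 0, fb = 0, rsd = 0))
  # hand arithmetic: errors +2, -2
  m2 <- forecast_metrics(c(12, 6), c(10, 8))
  expect_equal(m2$fb, 0)
  expect_equal(m2$rmse, 2)
  expect_equal(m2$rsd, 2)                 # population convention
  # underprediction is a positive error
  expect_gt(forecast_metrics(10, 8)$fb, 0)
  expect_equal(fb_abs(forecast_metrics(8, 10)), 2)
  # shifting predictions by +c shifts fb by -c, leaves rsd unchanged
  a <- rnorm(20, 100, 5); p <- rnorm(20, 100, 5)
  m3 <- forecast_metrics(a, p); m4 <- forecast_metrics(a, p + 3)
  expect_equal(m4$fb, m3$fb - 3)
  expect_equal(m4$rsd, m3$rsd)
  expect_error(forecast_metrics(1:3, 1:2), "mismatch")
})

test_that("the stationarity check rejects unit roots and flags trends", {
  set.seed(31)
  wn <- rnorm(500, 8000, 600)
  st <- check_stationarity(wn)
  expect_true(st$stationary)
  expect_lt(st$p_value, 0.05)
  expect_false(st$trivial)
  # rejection rate on white noise exceeds 95%
  rej <- vapply(1:40, function(i) {
    set.seed(i); check_stationarity(rnorm(300))$stationary
  }, logical(1))
  expect_gte(mean(rej), 0.95)
  # a pure trend is non-stationary under the constant-only spec
  tr <- seq(1, 100, length.out = 300) + rnorm(300, 0, 0.05)
  expect_false(check_stationarity(tr, spec = "C")$stationary)
  # constant series: degenerate, trivially stationary
  cs <- check_stationarity(rep(5000, 50))
  expect_true(cs$stationary)
  expect_true(cs$trivial)
})

test_that("noise-free AR(2) coefficients are recovered to 1e-6", {
  b <- c(50, 0.5, 0.3)
  x <- numeric(400); x[1:2] <- c(100, 120)
  for (t in 3:400) x[t] <- b[1] + b[2] * x[t - 1] + b[3] * x[t - 2]
  fit <- ar_fit(x, 2)
  expect_equal(unname(fit$coefficients), b, tolerance = 1e-6)
  # one-step prediction reproduces the next value
  expect_equal(ar_predict1(fit, x[1:399]), x[400], tolerance = 1e-6)
})

test_that("a constant series gives a perfect, correction-free forecast", {
  fr <- rem_walk_forward(rep(5000, 100), lag = 5, window = 3)
  expect_equal(fr$corrected_forecast, fr$base_forecast)
  expect_equal(fr$metrics_base$rmse, 0, tolerance = 1e-8)
  expect_equal(fr$metrics_corrected$fb, 0, tolerance = 1e-8)
  expect_error(rem_walk_forward(rep(1, 10), lag = 5, window = 3), "too short")
})

test_that("the residual correction is exactly additive", {
  set.seed(12)
  x <- as.numeric(arima.sim(list(ar = 0.7), 200)) + 50
  fr <- rem_walk_forward(x, lag = 3, window = 5)
  expect_equal(fr$corrected_forecast - fr$base_forecast, fr$estimated_error)
})

test_that("residual modeling improves structured-error forecasts on average", {
  # AR(1) signal whose innovations are themselves AR(1)-correlated, so the
  # one-step errors of the base carry structure the residual model can learn
  rmse_pair <- function(seed, base, lag) {
    set.seed(seed)
    n <- 250; u <- numeric(n); x <- numeric(n); eta <- rnorm(n)
    for (t in 2:n) { u[t] <- 0.8 * u[t - 1] + eta[t]; x[t] <- 0.6 * x[t - 1] + u[t] }
    fr <- rem_walk_forward(x, lag = lag, window = 5, base = base)
    c(base = fr$metrics_base$rmse, corrected = fr$metrics_corrected$rmse)
  }
  m <- vapply(1:25, rmse_pair, numeric(2), base = "persistence", lag = 1)
  expect_lte(mean(m["corrected", ]), mean(m["base", ]))
  m2 <- vapply(1:25, rmse_pair, numeric(2), base = "ar", lag = 1)
  expect_lte(mean(m2["corrected", ]), mean(m2["base", ]))
})

test_that("naive intervals have the reference arithmetic and linear width", {
  iv <- naive_interval(7369, sigma_h = 2600, c = 1.28)
  expect_equal(iv$half_width, 3328)
  expect_equal(round(iv$lower), 4041)
  expect_equal(round(iv$upper), 10697)
  # collapses at zero spread
  z <- naive_interval(100, sigma_h = 0)
  expect_equal(c(z$lower, z$upper), c(100, 100))
  # width linear in c and sigma
  expect_equal(naive_interval(0, sigma_h = 10, c = 2)$half_width, 20)
  expect_equal(naive_interval(0, sigma_h = 20, c = 1)$half_width, 20)
  expect_equal(naive_interval(0, sigma_h = 10, c = 1, h = 4,
                              inflate = TRUE)$half_width, 20)
  expect_error(naive_interval(10, series = c(1)), "sigma_h")
  # derivation from a series: sd of one-step naive errors
  s <- c(1, 3, 2, 5, 4)
  expect_equal(naive_interval(0, series = s, c = 1)$sigma_h, sd(diff(s)))
})

test_that("a seven-day interval table shares one sigma across the horizon", {
  tab <- interval_forecast_table(c(7369, 8879, 8202, 7557, 10199, 9819, 7426),
                                 sigma_h = 2600, c = 1.28)
  expect_equal(tab$half_width, rep(3328, 7))
  expect_equal(tab$upper - tab$point, rep(3328, 7))
  expect_equal(tab$point - tab$lower, rep(3328, 7))
})
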