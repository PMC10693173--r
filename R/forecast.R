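# Univariate daily-step forecasting: stationarity diagnostics, ordinary
# least-squares autoregression, walk-forward residual-error correction, the
# forecast metric suite, and naive-method prediction intervals.

#' Forecast error metrics
#'
#' Errors follow the convention `error = actual - predicted`, so a positive
#' mean error (forecast bias) means the model predicts too small.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return List with `rmse` (root mean squared error), `fb` (mean signed
#'   error), and `rsd` (population standard deviation of the errors).
#' @export
forecast_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 1) stop("empty input")
  e <- actual - predicted
  list(rmse = sqrt(mean(e^2)),
       fb = mean(e),
       rsd = sqrt(mean((e - mean(e))^2)))
}

#' Absolute forecast bias
#'
#' @param metrics A metrics list from [forecast_metrics()].
#' @return `abs(fb)`, the magnitude of the mean signed error.
#' @export
fb_abs <- function(metrics) abs(metrics$fb)

# Dickey-Fuller critical-value tables (constant-only and constant+trend
# regressions), finite-sample rows; p-values are obtained by interpolation,
# clamped to [0.01, 0.99].
.DF_PROBS <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.DF_N <- c(25, 50, 100, 250, 500, Inf)
.DF_C <- matrix(c(
  -3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60), 6, 8, byrow = TRUE)
.DF_CT <- matrix(c(
  -4.38, -3.95, -3.60, -3.24, -1.14, -0.80, -0.50, -0.15,
  -4.15, -3.80, -3.50, -3.18, -1.19, -0.87, -0.58, -0.24,
  -4.04, -3.73, -3.45, -3.15, -1.22, -0.90, -0.62, -0.28,
  -3.99, -3.69, -3.43, -3.13, -1.23, -0.92, -0.64, -0.31,
  -3.98, -3.68, -3.42, -3.13, -1.24, -0.93, -0.65, -0.32,
  -3.96, -3.66, -3.41, -3.12, -1.25, -0.94, -0.66, -0.33), 6, 8, byrow = TRUE)

.df_pvalue <- function(stat, n, spec) {
  tab <- if (spec == "CT") .DF_CT else .DF_C
  crit <- vapply(seq_along(.DF_PROBS), function(j)
    stats::approx(.DF_N[-6], tab[-6, j], xout = min(n, 500), rule = 2)$y,
    numeric(1))
  p <- stats::approx(crit, .DF_PROBS, xout = stat, rule = 2)$y
  min(max(p, 0.01), 0.99)
}

# One augmented Dickey-Fuller regression: delta y_t on y_{t-1}, lagged
# deltas, a constant and (for "CT") a linear trend.  Returns the t statistic
# on y_{t-1}.
.adf_stat <- function(y, spec, lags) {
  dy <- diff(y)
  n <- length(dy)
  if (n - lags < 5) return(NULL)
  idx <- (lags + 1):n
  X <- cbind(ylag = y[idx], const = 1)
  if (spec == "CT") X <- cbind(X, trend = idx)
  if (lags > 0)
    for (j in seq_len(lags)) X <- cbind(X, dy[idx - j])
  yy <- dy[idx]
  fit <- stats::lm.fit(X, yy)
  res <- fit$residuals
  df <- length(yy) - fit$rank
  if (df <= 0) return(NULL)
  s2 <- sum(res^2) / df
  XtXinv <- tryCatch(chol2inv(chol(crossprod(X[, seq_len(fit$rank), drop = FALSE]))),
                     error = function(e) NULL)
  if (is.null(XtXinv)) return(NULL)
  se <- sqrt(s2 * XtXinv[1, 1])
  tstat <- fit$coefficients[1] / se
  k <- fit$rank
  rss <- sum(res^2)
  aic <- length(yy) * log(rss / length(yy)) + 2 * k
  list(stat = unname(tstat), aic = aic, lags = lags, nobs = length(yy))
}

#' Augmented Dickey-Fuller stationarity check
#'
#' Lag order is chosen by AIC (up to the usual `12 * (n/100)^0.25` ceiling)
#' and the test is run under both the constant-only (`"C"`) and
#' constant-plus-trend (`"CT"`) regression specifications; the series is
#' declared stationary when the p-value under the chosen specification is
#' below `alpha`.  A constant series is degenerate and is reported as
#' trivially stationary.
#'
#' @param series Numeric series, length >= 20.
#' @param spec Which specification drives the `stationary` verdict,
#'   `"C"` (default) or `"CT"`.
#' @param alpha Significance level (default 0.05).
#' @return List with `stationary`, `p_value`, `statistic`, `lags`,
#'   `regression_spec`, `trivial`, and a `by_spec` list holding both
#'   specifications' results.
#' @export
check_stationarity <- function(series, spec = c("C", "CT"), alpha = 0.05) {
  spec <- match.arg(spec)
  series <- as.numeric(series)
  if (any(!is.finite(series))) stop("series contains non-finite values")
  if (length(series) < 20) stop("series must have length >= 20")
  if (stats::sd(series) == 0) {
    return(list(stationary = TRUE, p_value = NA_real_, statistic = NA_real_,
                lags = 0L, regression_spec = spec, trivial = TRUE,
                by_spec = NULL))
  }
  max_lag <- max(1L, floor(12 * (length(series) / 100)^0.25))
  one_spec <- function(sp) {
    fits <- Filter(Negate(is.null),
                   lapply(0:max_lag, function(l) .adf_stat(series, sp, l)))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
    p <- .df_pvalue(best$stat, best$nobs, sp)
    list(statistic = best$stat, p_value = p, lags = best$lags)
  }
  by_spec <- list(C = one_spec("C"), CT = one_spec("CT"))
  chosen <- by_spec[[spec]]
  list(stationary = chosen$p_value < alpha, p_value = chosen$p_value,
       statistic = chosen$statistic, lags = chosen$lags,
       regression_spec = spec, trivial = FALSE, by_spec = by_spec)
}

#' Fit an autoregression of order p by ordinary least squares
#'
#' `X(t) = b0 + b1 X(t-1) + ... + bp X(t-p)`; on a noise-free AR(p) series
#' the generator's coefficients are recovered exactly.
#'
#' @param series Numeric series, length > p + 1.
#' @param p Lag order (>= 1).
#' @return Object of class `ar_model`: list with `coefficients`
#'   (`b0, b1, ..., bp`) and `p`.
#' @export
ar_fit <- function(series, p) {
  stopifnot(p >= 1, length(series) > p + 1)
  emb <- stats::embed(as.numeric(series), p + 1)
  y <- emb[, 1]
  X <- cbind(1, emb[, -1, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  structure(list(coefficients = stats::setNames(b, paste0("b", 0:p)), p = p),
            class = "ar_model")
}

#' One-step prediction from an AR model
#'
#' @param model An [ar_fit()] result.
#' @param history Numeric vector of past values, most recent last; at least
#'   `p` values are required.
#' @return The one-step-ahead prediction.
#' @export
ar_predict1 <- function(model, history) {
  p <- model$p
  if (length(history) < p) stop("history shorter than the lag order")
  lags <- rev(utils::tail(history, p))
  unname(model$coefficients[1] + sum(model$coefficients[-1] * lags))
}

#' Walk-forward forecasting with residual-error minimization
#'
#' The series is split 60/20/20 into train/validation/test in temporal order
#' (no shuffling).  A base forecaster -- an AR(`lag`) model fitted on
#' train+validation, or the persistence model `x_hat(t) = x(t-1)` -- produces
#' one-step forecasts.  Its in-sample residual series is modelled by an
#' AR(`window`) over errors; walking forward over the test set, each base
#' forecast is corrected by the residual model's one-step error estimate
#' (`improved = forecast + estimated error`), with observed errors appended
#' as the walk advances.  Metrics for the corrected and uncorrected
#' forecasts are both returned.
#'
#' @param series Daily step series, length > lag + window + 10.
#' @param split Train/validation/test fractions (default `c(.6, .2, .2)`).
#' @param lag Base AR order (14 suits month-scale series, 50 longer ones).
#' @param window Residual AR order (default 5).
#' @param base `"ar"` (default) or `"persistence"`.
#' @return Object of class `forecast_result`: per-test-day `actual`,
#'   `base_forecast`, `corrected_forecast`, `estimated_error`, the fitted
#'   models, and `metrics_base` / `metrics_corrected`.
#' @export
rem_walk_forward <- function(series, split = c(0.6, 0.2, 0.2), lag = 14,
                             window = 5, base = c("ar", "persistence")) {
  base <- match.arg(base)
  series <- as.numeric(series)
  if (any(!is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  if (n <= lag + window + 10) stop("series too short for lag/window settings")
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-8)
  fit_end <- floor((split[1] + split[2]) * n)   # train + validation
  test_idx <- (fit_end + 1):n
  # base forecaster and its in-sample one-step residuals on the fit span
  if (base == "ar") {
    bm <- ar_fit(series[1:fit_end], lag)
    fitted1 <- vapply((lag + 1):fit_end, function(t)
      ar_predict1(bm, series[1:(t - 1)]), numeric(1))
    resid_hist <- series[(lag + 1):fit_end] - fitted1
    base_fc <- vapply(test_idx, function(t)
      ar_predict1(bm, series[1:(t - 1)]), numeric(1))
  } else {
    bm <- structure(list(coefficients = c(b0 = 0, b1 = 1), p = 1L),
                    class = "ar_model")
    resid_hist <- diff(series[1:fit_end])
    base_fc <- series[test_idx - 1]
  }
  # residual model: AR(window) over the error series
  rm_model <- if (stats::sd(resid_hist) > 0 && length(resid_hist) > window + 1)
    ar_fit(resid_hist, window)
  else structure(list(coefficients = stats::setNames(rep(0, window + 1),
                                                     paste0("b", 0:window)),
                      p = window), class = "ar_model")
  est_err <- numeric(length(test_idx))
  errs <- resid_hist
  for (i in seq_along(test_idx)) {
    est_err[i] <- ar_predict1(rm_model, errs)
    errs <- c(errs, series[test_idx[i]] - base_fc[i])   # walk forward
  }
  corrected <- base_fc + est_err
  actual <- series[test_idx]
  structure(list(actual = actual, base_forecast = base_fc,
                 corrected_forecast = corrected, estimated_error = est_err,
                 base_model = bm, residual_model = rm_model,
                 lag = lag, window = window, base = base,
                 test_index = test_idx,
                 metrics_base = forecast_metrics(actual, base_fc),
                 metrics_corrected = forecast_metrics(actual, corrected)),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> base=%s lag=%d window=%d, %d test days\n",
              x$base, x$lag, x$window, length(x$actual)))
  cat(sprintf("  base:      RMSE %.2f  FB %+.2f  RSD %.2f\n",
              x$metrics_base$rmse, x$metrics_base$fb, x$metrics_base$rsd))
  cat(sprintf("  corrected: RMSE %.2f  FB %+.2f  RSD %.2f\n",
              x$metrics_corrected$rmse, x$metrics_corrected$fb,
              x$metrics_corrected$rsd))
  invisible(x)
}

#' Naive-method prediction interval
#'
#' Builds the interval `point +/- c * sigma_h`.  When `sigma_h` is not
#' supplied it is derived as the standard deviation of the one-step naive
#' forecast errors `x_t - x_{t-1}` of `series`.  By default `sigma_h` is
#' held constant across a multi-day horizon; `inflate = TRUE` applies the
#' naive method's `sqrt(h)` widening instead.
#'
#' @param point Point forecast (steps).
#' @param series Optional daily step series used to derive `sigma_h`.
#' @param sigma_h Optional residual standard deviation override.
#' @param c Coverage constant (default 1.28, the 80% normal-error interval).
#' @param h Forecast horizon in days (default 1).
#' @param inflate Apply `sqrt(h)` widening (default `FALSE`).
#' @return Object of class `prediction_interval` with `point`, `lower`,
#'   `upper`, `c`, `sigma_h`, `h`.
#' @export
naive_interval <- function(point, series = NULL, sigma_h = NULL, c = 1.28,
                           h = 1, inflate = FALSE) {
  stopifnot(is.finite(point), c >= 0, h > 0)
  if (is.null(sigma_h)) {
    if (is.null(series) || length(series) < 2)
      stop("need `sigma_h` or a series of length >= 2 to derive it")
    sigma_h <- stats::sd(diff(as.numeric(series)))
  }
  if (sigma_h < 0) stop("`sigma_h` must be >= 0")
  half <- c * sigma_h * if (inflate) sqrt(h) else 1
  structure(list(point = point, lower = point - half, upper = point + half,
                 c = c, sigma_h = sigma_h, h = h, half_width = half),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("<prediction_interval> %s +/- %s  (c=%.2f, sigma_h=%.2f, h=%d)\n",
              format(round(x$point)), format(round(x$half_width)),
              x$c, x$sigma_h, as.integer(x$h)))
  invisible(x)
}

#' Seven-day interval forecast table
#'
#' Convenience wrapper: one [naive_interval()] per point forecast, sharing a
#' single `sigma_h`.
#'
#' @param points Vector of point forecasts.
#' @inheritParams naive_interval
#' @return Data frame with `day`, `point`, `lower`, `upper`, `half_width`
#'   (bounds rounded to integer steps for display; use [naive_interval()]
#'   for exact values).
#' @export
interval_forecast_table <- function(points, series = NULL, sigma_h = NULL,
                                    c = 1.28, inflate = FALSE) {
  rows <- lapply(seq_along(points), function(h) {
    iv <- naive_interval(points[h], series = series, sigma_h = sigma_h,
                         c = c, h = h, inflate = inflate)
    data.frame(day = h, point = iv$point, lower = round(iv$lower),
               upper = round(iv$upper), half_width = round(iv$half_width))
  })
  do.call(rbind, rows)
}
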