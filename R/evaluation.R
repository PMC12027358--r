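#' Mean squared forecast error
#'
#' Computed on mortality levels (per 100,000 or per 1,000), not logs:
#' \eqn{\frac{1}{N}\sum_t (\hat y_t - y_t)^2}.
#'
#' @param actual,forecast equal-length numeric series.
#' @return Non-negative scalar.
#' @export
mse <- function(actual, forecast) {
  if (length(actual) == 0L) stop("empty series", call. = FALSE)
  if (length(actual) != length(forecast))
    stop("actual and forecast lengths differ", call. = FALSE)
  mean((forecast - actual)^2)
}

#' Campbell-Thompson out-of-sample R-squared
#'
#' `1 - mse_unrestricted / mse_restricted`. Positive when the unrestricted
#' (predictive) model out-forecasts the restricted benchmark; never
#' exceeds 1.
#'
#' @param mse_unrestricted MSE of the predictive model's forecasts.
#' @param mse_restricted MSE of the benchmark's forecasts.
#' @return Scalar in (-Inf, 1].
#' @export
oos_r2 <- function(mse_unrestricted, mse_restricted) {
  stopifnot(mse_unrestricted >= 0, mse_restricted >= 0)
  if (mse_restricted == 0) {
    if (mse_unrestricted == 0) return(0)
    stop("restricted-model MSE is zero while unrestricted is not: ",
         "comparison undefined", call. = FALSE)
  }
  1 - mse_unrestricted / mse_restricted
}

#' Historical-average benchmark forecast
#'
#' The restricted historical-average model forecasts every future year at
#' the geometric mean of the training levels (the mean of the log levels,
#' exponentiated) — the log-space analogue of the usual historical mean,
#' consistent with the log-space predictive model so that all MSEs compare
#' like with like after identical back-transforms.
#'
#' @param training positive numeric vector of observed outcome levels.
#' @return Scalar forecast level.
#' @examples
#' ha_forecast(c(100, 400))  # 200
#' @export
ha_forecast <- function(training) {
  if (length(training) == 0L) stop("empty training series", call. = FALSE)
  stopifnot(all(training > 0))
  exp(mean(log(training)))
}

#' ARIMA benchmark one-step forecast
#'
#' Fits an ARIMA model to the log levels and returns the one-step-ahead
#' forecast back-transformed by exponentiation. By default the order is
#' selected by AIC over the grid p in 0..2, d in 0..1, q in 0..1; a
#' non-convergent or degenerate fit (e.g. zero-variance training) falls
#' back to the (0,1,0) random walk — forecast equal to the last observed
#' level — with a warning.
#'
#' @param training positive numeric vector of observed outcome levels
#'   (length >= 10).
#' @param order optional fixed `c(p, d, q)`; `NULL` selects by AIC.
#' @return Scalar forecast level.
#' @export
arima_forecast <- function(training, order = NULL) {
  if (length(training) < 10L)
    stop("ARIMA benchmark needs at least 10 training observations",
         call. = FALSE)
  stopifnot(all(training > 0))
  ly <- log(training)
  fit_one <- function(ord) {
    tryCatch(suppressWarnings(stats::arima(ly, order = ord)),
             error = function(e) NULL)
  }
  fallback <- function() {
    warning("ARIMA fit failed; falling back to (0,1,0) random walk",
            call. = FALSE)
    training[length(training)]
  }
  if (stats::var(ly) == 0) return(fallback())
  if (is.null(order)) {
    grid <- expand.grid(p = 0:2, d = 0:1, q = 0:1)
    fits <- apply(grid, 1L, function(o) fit_one(unname(o)))
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else stats::AIC(f),
                   numeric(1))
    if (all(is.infinite(aics))) return(fallback())
    best <- fits[[which.min(aics)]]
  } else {
    if (all(order == c(0, 1, 0))) return(training[length(training)])
    best <- fit_one(order)
    if (is.null(best)) return(fallback())
  }
  as.numeric(exp(stats::predict(best, n.ahead = 1L)$pred))
}

#' Recursive out-of-sample evaluation against benchmark models
#'
#' Runs the expanding-window one-step evaluation of the predictive
#' (unrestricted) model and of each restricted benchmark — historical
#' average and/or ARIMA — over identical evaluation years, and assembles
#' mean squared errors and the Campbell-Thompson out-of-sample R-squared
#' per benchmark. Every benchmark forecast for an evaluation year uses
#' exactly the observations preceding that year, like the unrestricted
#' model's refit.
#'
#' @inheritParams recursive_oos_evaluation
#' @param benchmarks subset of `c("HA", "ARIMA")`.
#' @return An `evaluation_report`: list with `n`, `fraction`, `window`
#'   (`"recursive"`), `estimator`, `mse_unrestricted`, `mse_restricted`
#'   (named), `oos_r2` (named), and the `forecasts` data frame (columns
#'   `year`, `actual`, `unrestricted`, one per benchmark).
#' @export
evaluate <- function(panel, outcome, fraction,
                     estimator = c("FQGLS", "OLS"),
                     benchmarks = c("HA", "ARIMA")) {
  estimator <- match.arg(estimator)
  benchmarks <- match.arg(benchmarks, several.ok = TRUE)
  unres <- recursive_oos_evaluation(panel, outcome, fraction, estimator)
  levels <- outcome_series(panel, outcome)
  eval_idx <- match(unres$year, panel$year)
  bench <- lapply(benchmarks, function(b) {
    vapply(eval_idx, function(i) {
      train <- levels[seq_len(i - 1L)]
      if (b == "HA") ha_forecast(train) else arima_forecast(train)
    }, numeric(1))
  })
  names(bench) <- benchmarks
  mse_u <- mse(unres$actual, unres$forecast)
  mse_r <- vapply(bench, function(f) mse(unres$actual, f), numeric(1))
  report <- list(country = panel_country(panel), outcome = outcome,
                 n = nrow(unres), fraction = fraction,
                 window = "recursive", estimator = estimator,
                 mse_unrestricted = mse_u,
                 mse_restricted = mse_r,
                 oos_r2 = vapply(mse_r, function(m) oos_r2(mse_u, m),
                                 numeric(1)),
                 forecasts = cbind(
                   data.frame(year = unres$year, actual = unres$actual,
                              unrestricted = unres$forecast),
                   as.data.frame(bench)))
  structure(report, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Recursive out-of-sample evaluation: %s, %s mortality (%s, %.0f%% split)\n",
    x$country, x$outcome, x$estimator, 100 * x$fraction))
  cat(sprintf("  N = %d one-step forecasts\n", x$n))
  cat(sprintf("  MSE (unrestricted): %.4g\n", x$mse_unrestricted))
  for (b in names(x$mse_restricted))
    cat(sprintf("  MSE (%s): %.4g   OOS R2 vs %s: %.4f\n",
                b, x$mse_restricted[[b]], b, x$oos_r2[[b]]))
  invisible(x)
}
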