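# Design matrix of the dynamic double-log predictive regression:
#   log Y_t = alpha + beta*log X_{t-1} + theta*dlog X_t + gamma*log Y_{t-1}
# over t = 2..T (one observation consumed by the lag).
build_design <- function(panel, outcome) {
  y <- log(outcome_series(panel, outcome))
  x <- log(panel$phe)
  T_ <- length(y)
  idx <- 2:T_
  X <- cbind(`(Intercept)` = 1,
             lag_log_phe = x[idx - 1L],
             dlog_phe = x[idx] - x[idx - 1L],
             lag_log_outcome = y[idx - 1L])
  list(X = X, y = y[idx], years = panel$year[idx])
}

# plain least squares with conventional standard errors; errors on rank
# deficiency (e.g. a constant outcome makes the lagged outcome collinear
# with the intercept)
ls_core <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("degenerate design: regressors are collinear ",
         "(is the outcome series constant?)", call. = FALSE)
  coef <- qr.coef(qx, y)
  resid <- as.numeric(y - X %*% coef)
  dfres <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / dfres
  vcov <- sigma2 * chol2inv(qr.R(qx))
  list(coef = coef, residuals = resid,
       std_errors = stats::setNames(sqrt(diag(vcov)), colnames(X)),
       sigma2 = sigma2, df_residual = dfres)
}

new_predictive_fit <- function(core, design, panel, outcome, estimator,
                               cond_sd) {
  structure(list(
    alpha = unname(core$coef[1]), beta = unname(core$coef[2]),
    theta = unname(core$coef[3]), gamma = unname(core$coef[4]),
    coefficients = core$coef,
    std_errors = core$std_errors,
    residuals = stats::setNames(core$residuals, design$years),
    cond_sd = cond_sd,
    estimator = estimator,
    outcome = outcome,
    country = panel_country(panel),
    years = design$years,
    n_obs = length(design$y),
    df_residual = core$df_residual),
    class = "predictive_fit")
}

#' @export
print.predictive_fit <- function(x, ...) {
  cat(sprintf("Dynamic log-log predictive fit (%s), %s mortality, %s\n",
              x$estimator, x$outcome, x$country))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$std_errors)
  print(round(tab, 4))
  cat(sprintf("n = %d usable years (%d-%d)\n",
              x$n_obs, min(x$years), max(x$years)))
  invisible(x)
}

check_estimable <- function(panel, outcome) {
  stopifnot(is_country_panel(panel))
  match_outcome(outcome)
  if (nrow(panel) < 10L)
    stop("panel for ", panel_country(panel),
         " too short for estimation (need >= 10 years, have ",
         nrow(panel), ")", call. = FALSE)
}

#' Fit the dynamic predictive model by ordinary least squares
#'
#' Regresses the log mortality outcome on an intercept, the lagged log PHE
#' level, the contemporaneous change in log PHE, and the lagged log outcome,
#' over the panel years 2..T (natural logs throughout). The coefficient on
#' lagged log PHE (`beta`) carries the substantive hypothesis: negative when
#' higher public health spending predicts lower mortality.
#'
#' @param panel a [country_panel] with at least 10 years.
#' @param outcome `"maternal"` or `"child"`.
#' @return A `predictive_fit` with elements `alpha`, `beta`, `theta`,
#'   `gamma`, `residuals`, `std_errors`, `cond_sd` (all 1 for OLS) and
#'   `estimator = "OLS"`.
#' @seealso [fit_fqgls()] for the heteroskedasticity-weighted estimator.
#' @export
fit_ols <- function(panel, outcome) {
  check_estimable(panel, outcome)
  d <- build_design(panel, outcome)
  core <- ls_core(d$X, d$y)
  new_predictive_fit(core, d, panel, match_outcome(outcome), "OLS",
                     cond_sd = rep(1, length(d$y)))
}

#' Fit an ARCH conditional-variance model to regression residuals
#'
#' Estimates \eqn{\sigma_t^2 = a_0 + \sum_q a_q \varepsilon_{t-q}^2} by
#' least squares of the squared residuals on their own lags. Lag
#' coefficients are clipped at zero, and (by default) zeroed unless their
#' estimate is positive and one-sided significant at `sig_level`, so that
#' series without detectable ARCH structure yield constant variances and
#' downstream weighting collapses to OLS. When every lag coefficient is
#' zeroed the variances all equal the residual sample variance (mean of the
#' squared residuals). Fitted variances for the first `order` observations,
#' where lags are unavailable, are set to that sample variance. All
#' variances are floored at `(0.01 * sd(residuals))^2`.
#'
#' @param residuals numeric residual series (from [fit_ols()]).
#' @param order ARCH order (default 1).
#' @param sig_level one-sided significance level for retaining a lag
#'   coefficient; `1` disables the screen (pure non-negativity clipping).
#' @return List with `variances` (same length as `residuals`), the clipped
#'   coefficients `a0` and `a` (lag coefficients), and `floor`.
#' @export
fit_conditional_variance <- function(residuals, order = 1L,
                                     sig_level = 0.05) {
  order <- as.integer(order)
  stopifnot(order >= 1L, sig_level > 0, sig_level <= 1)
  n <- length(residuals)
  if (n < order + 5L)
    stop("insufficient residuals for ARCH(", order, ") fit: need at least ",
         order + 5L, ", have ", n, call. = FALSE)
  e2 <- residuals^2
  s2 <- mean(e2)
  flo <- (0.01 * stats::sd(residuals))^2
  idx <- (order + 1L):n
  X <- cbind(1, vapply(seq_len(order), function(q) e2[idx - q],
                       numeric(length(idx))))
  fit <- ls_core(X, e2[idx])
  a <- pmax(fit$coef[-1], 0)
  if (sig_level < 1) {
    tstat <- fit$coef[-1] / fit$std_errors[-1]
    crit <- stats::qt(1 - sig_level, df = fit$df_residual)
    a[tstat <= crit] <- 0
  }
  if (all(a == 0)) {
    v <- rep(s2, n)
    a0 <- s2
  } else {
    a0 <- max(fit$coef[1], 0)
    v <- rep(s2, n)
    for (t in idx)
      v[t] <- a0 + sum(a * e2[t - seq_len(order)])
  }
  v <- pmax(v, flo)
  list(variances = v, a0 = unname(a0), a = unname(a), floor = flo)
}

#' Fit the dynamic predictive model by Feasible Quasi-Generalised Least
#' Squares
#'
#' Two-step estimator robust to conditional heteroskedasticity with
#' persistent regressors: (1) fit by OLS; (2) fit an ARCH(`order`)
#' conditional-variance model to the OLS residuals; (3) divide every
#' regression row — response and all regressors, including the intercept
#' column — by the fitted conditional standard deviation; (4) re-estimate by
#' least squares on the weighted system. When the variance fit finds no
#' ARCH structure the weights are constant and the estimate coincides with
#' OLS exactly; when the variance fit is degenerate (e.g. zero residual
#' variance) the function falls back to OLS with a warning.
#'
#' @inheritParams fit_ols
#' @param order ARCH order for the variance step.
#' @return A `predictive_fit` with `estimator = "FQGLS"` and `cond_sd` the
#'   per-observation conditional standard deviations used as weights (or
#'   the OLS fit after a degenerate variance step).
#' @export
fit_fqgls <- function(panel, outcome, order = 1L) {
  ols <- fit_ols(panel, outcome)
  cv <- tryCatch(fit_conditional_variance(ols$residuals, order = order),
                 error = function(e) e)
  if (inherits(cv, "error") || any(!is.finite(cv$variances)) ||
      any(cv$variances <= 0)) {
    warning("conditional-variance fit degenerate for ",
            panel_country(panel), " (", outcome, "); falling back to OLS",
            call. = FALSE)
    return(ols)
  }
  sd_t <- sqrt(cv$variances)
  d <- build_design(panel, outcome)
  w <- 1 / sd_t
  core <- ls_core(d$X * w, d$y * w)
  # store residuals on the original (unweighted) scale
  core$residuals <- as.numeric(d$y - d$X %*% core$coef)
  fit <- new_predictive_fit(core, d, panel, match_outcome(outcome),
                            "FQGLS", cond_sd = sd_t)
  fit$arch <- cv[c("a0", "a", "floor")]
  fit
}

#' Screen the estimated PHE-mortality relationship
#'
#' A country is flagged `nil` when its estimated coefficient on lagged log
#' PHE is non-negative — under such a fit higher spending is not projected
#' to reduce mortality, and no scenario forecast is issued for it
#' (rendered as "Nil" in forecast tables). The sign of the point estimate
#' alone decides, regardless of significance. Separately,
#' `already_below_targets` marks countries whose observed maternal series
#' stayed below 70 and child series below 25 throughout the sample; such
#' countries are conventionally excluded from the analysis outright.
#'
#' @param fit a `predictive_fit`.
#' @param panel the [country_panel] the fit came from.
#' @return A list of class `relationship_screen` with `beta_sign`
#'   (`"negative"` or `"non-negative"`), `nil`, and
#'   `already_below_targets`.
#' @export
screen_relationship <- function(fit, panel) {
  stopifnot(inherits(fit, "predictive_fit"), is_country_panel(panel))
  nil <- fit$beta >= 0
  structure(list(
    country = panel_country(panel),
    outcome = fit$outcome,
    beta = fit$beta,
    beta_sign = if (nil) "non-negative" else "negative",
    nil = nil,
    already_below_targets =
      all(panel$maternal < sdg_threshold("maternal")) &&
      all(panel$child < sdg_threshold("child"))),
    class = "relationship_screen")
}

# significance stars from a two-sided t test: 1% ***, 5% **, 10% *
significance_stars <- function(estimate, se, df) {
  p <- 2 * stats::pt(abs(estimate / se), df = df, lower.tail = FALSE)
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}
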