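# subset a panel by row index, keeping the country_panel class
panel_window <- function(panel, idx) {
  country_panel(panel_country(panel), panel$year[idx], panel$phe[idx],
                panel$maternal[idx], panel$child[idx])
}

#' Split a panel into training and evaluation segments
#'
#' The first `floor(fraction * T)` years form the training segment, the
#' remainder the evaluation segment; both contiguous. The canonical splits
#' are 50 and 75 percent of the observations.
#'
#' @param panel a [country_panel].
#' @param fraction split fraction in (0, 1).
#' @return List with `train` (a [country_panel]) and `eval` (a data frame
#'   of the held-out years; possibly zero rows).
#' @export
split_window <- function(panel, fraction) {
  stopifnot(is_country_panel(panel), fraction > 0, fraction < 1)
  n_train <- floor(fraction * nrow(panel))
  if (n_train < 10L)
    stop("training segment too short: floor(", fraction, " * ",
         nrow(panel), ") = ", n_train, " < 10", call. = FALSE)
  list(train = panel_window(panel, seq_len(n_train)),
       eval = as.data.frame(panel)[seq.int(n_train + 1L, length.out =
                                             nrow(panel) - n_train), ,
                                   drop = FALSE])
}

#' In-sample fitted mortality levels
#'
#' Fitted log values of the dynamic regression, back-transformed by plain
#' exponentiation, paired with the actual levels over years 2..T (the first
#' year is consumed by the lag).
#'
#' @param fit a `predictive_fit` produced from `panel`.
#' @param panel the [country_panel] the fit came from.
#' @return Data frame with columns `year`, `actual`, `fitted`.
#' @export
in_sample_fitted <- function(fit, panel) {
  stopifnot(inherits(fit, "predictive_fit"), is_country_panel(panel))
  if (!identical(fit$country, panel_country(panel)) ||
      fit$n_obs != nrow(panel) - 1L)
    stop("fit does not match panel (country or length differ)",
         call. = FALSE)
  d <- build_design(panel, fit$outcome)
  data.frame(year = d$years,
             actual = exp(d$y),
             fitted = as.numeric(exp(d$X %*% fit$coefficients)))
}

#' Specify a PHE growth scenario
#'
#' A scenario assumes the PHE per capita level grows by a fixed proportion
#' `g` every year from the last observed level, compounding
#' multiplicatively: the level at horizon h is `base * (1 + g)^h`. The
#' canonical scenarios are g = 0.10, 0.20, 0.30 projected from 2020 to
#' 2030.
#'
#' @param g yearly proportional PHE growth, `g > -1`.
#' @param base_year last observed year.
#' @param end_year final forecast year, `> base_year`.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(g, base_year = 2020L, end_year = 2030L) {
  stopifnot(is.numeric(g), length(g) == 1L)
  if (g <= -1) stop("g must exceed -1", call. = FALSE)
  base_year <- as.integer(base_year); end_year <- as.integer(end_year)
  if (end_year <= base_year)
    stop("end_year must exceed base_year", call. = FALSE)
  structure(list(g = g, base_year = base_year, end_year = end_year),
            class = "scenario_spec")
}

#' Compounded PHE path under a scenario
#'
#' @param base_phe last observed PHE level (> 0).
#' @param scenario a [scenario_spec()].
#' @return Named numeric vector of projected PHE levels for the years
#'   `base_year + 1` .. `end_year`, with `base * (1+g)^h` at horizon h.
#' @examples
#' scenario_path(100, scenario_spec(0.10, 2020, 2023))  # 110, 121, 133.1
#' @export
scenario_path <- function(base_phe, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"), base_phe > 0)
  h <- seq_len(scenario$end_year - scenario$base_year)
  stats::setNames(base_phe * (1 + scenario$g)^h, scenario$base_year + h)
}

#' Recursive scenario forecast of mortality to the horizon
#'
#' Iterates the fitted dynamic equation forward from the last observed
#' year, feeding each forecast back in as the lagged outcome:
#' \deqn{\log \hat Y_t = \alpha + \beta \log X_{t-1} + \theta \log(1+g)
#'       + \gamma \log \hat Y_{t-1}}
#' with X following the compounded scenario path (so the change in log PHE
#' is the constant log(1+g)) and the recursion seeded at the observed
#' outcome level in the base year. Levels are recovered by plain
#' exponentiation; no bias correction is applied, and reported tables round
#' to the nearest integer. A `nil` fit (non-negative PHE coefficient)
#' yields a path with no mortality forecast, mirroring the "Nil" rows of
#' published tables.
#'
#' @param fit a `predictive_fit`.
#' @param last_phe observed PHE level in the base year (> 0).
#' @param last_outcome observed mortality level in the base year (> 0).
#' @param scenario a [scenario_spec()].
#' @param nil logical; defaults to the sign screen `fit$beta >= 0`.
#' @return A `forecast_path`: list with `country`, `outcome`, `scenario`,
#'   `years`, `phe_path`, `mortality` (raw levels, `NULL` when nil),
#'   `mortality_rounded`, and `nil`.
#' @export
recursive_forecast <- function(fit, last_phe, last_outcome, scenario,
                               nil = fit$beta >= 0) {
  stopifnot(inherits(fit, "predictive_fit"),
            inherits(scenario, "scenario_spec"),
            last_phe > 0, last_outcome > 0)
  phe_path <- scenario_path(last_phe, scenario)
  years <- as.integer(names(phe_path))
  out <- structure(list(country = fit$country, outcome = fit$outcome,
                        scenario = scenario, years = years,
                        phe_path = phe_path, mortality = NULL,
                        mortality_rounded = NULL, nil = nil),
                   class = "forecast_path")
  if (nil) return(out)
  lx <- log(c(last_phe, phe_path))  # lx[h] is log X at years[h] - 1
  dlx <- log(1 + scenario$g)
  ly <- numeric(length(years))
  prev <- log(last_outcome)
  for (h in seq_along(years)) {
    prev <- fit$alpha + fit$beta * lx[h] + fit$theta * dlx +
      fit$gamma * prev
    ly[h] <- prev
  }
  out$mortality <- stats::setNames(exp(ly), years)
  out$mortality_rounded <- round(out$mortality)
  out
}

#' @export
print.forecast_path <- function(x, ...) {
  cat(sprintf("Scenario forecast: %s, %s mortality, g = %.0f%%\n",
              x$country, x$outcome, 100 * x$scenario$g))
  if (x$nil) {
    cat("  Nil (non-negative PHE-mortality relationship; no forecast)\n")
  } else {
    print(round(x$mortality, 1))
  }
  invisible(x)
}

#' Recursive (expanding-window) out-of-sample evaluation forecasts
#'
#' For every year of the evaluation segment the model is re-estimated on
#' all data up to the preceding year and a one-step-ahead forecast is
#' produced using the observed PHE values (scenario paths play no role in
#' validation). Each forecast therefore comes from a strictly larger
#' training set than the one before.
#'
#' @param panel a [country_panel].
#' @param outcome `"maternal"` or `"child"`.
#' @param fraction training fraction handed to [split_window()].
#' @param estimator `"FQGLS"` or `"OLS"`.
#' @return Data frame with columns `year`, `actual`, `forecast` over the
#'   evaluation years, with attribute `fraction`.
#' @export
recursive_oos_evaluation <- function(panel, outcome, fraction,
                                     estimator = c("FQGLS", "OLS")) {
  estimator <- match.arg(estimator)
  sw <- split_window(panel, fraction)
  n_train <- nrow(sw$train)
  T_ <- nrow(panel)
  if (n_train >= T_)
    stop("no evaluation years left after the split", call. = FALSE)
  y <- log(outcome_series(panel, outcome))
  x <- log(panel$phe)
  res <- lapply(seq.int(n_train + 1L, T_), function(i) {
    f <- if (estimator == "FQGLS")
      fit_fqgls(panel_window(panel, seq_len(i - 1L)), outcome)
    else fit_ols(panel_window(panel, seq_len(i - 1L)), outcome)
    lhat <- f$alpha + f$beta * x[i - 1L] + f$theta * (x[i] - x[i - 1L]) +
      f$gamma * y[i - 1L]
    data.frame(year = panel$year[i], actual = exp(y[i]),
               forecast = exp(lhat))
  })
  out <- do.call(rbind, res)
  attr(out, "fraction") <- fraction
  attr(out, "estimator") <- estimator
  out
}
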