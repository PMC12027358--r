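#' Configuration of the synthetic panel data-generating process
#'
#' The generator reproduces the statistical structure the estimation and
#' forecasting stages assume: a persistent (near-unit-root) positive PHE
#' series and a mortality outcome following the dynamic double-log model
#'
#' \deqn{\log Y_t = \alpha + \beta \log X_{t-1} + \theta \Delta\log X_t
#'       + \gamma \log Y_{t-1} + \varepsilon_t}
#'
#' with X the PHE level and Y the mortality level. Log PHE evolves as a
#' drifting random walk whose innovations are AR(1) with coefficient
#' `phe_rho`, i.e. \eqn{\log X_t = \log X_{t-1} + d + u_t},
#' \eqn{u_t = \rho u_{t-1} + v_t}. The outcome noise is i.i.d. normal, or
#' ARCH(1) when `arch_a1 > 0`:
#' \eqn{\varepsilon_t = \sigma_t z_t}, \eqn{\sigma_t^2 = a_0 + a_1
#' \varepsilon_{t-1}^2}.
#'
#' @param alpha intercept of the outcome equation.
#' @param beta coefficient on lagged log PHE; negative when higher spending
#'   reduces mortality.
#' @param theta coefficient on the contemporaneous change in log PHE.
#' @param gamma coefficient on the lagged log outcome; `|gamma| < 1` gives a
#'   stable recursion (`gamma = 1` is allowed to emulate unit-root
#'   persistence and is flagged with a warning).
#' @param phe_start initial PHE level (> 0).
#' @param phe_drift mean yearly log-PHE growth.
#' @param phe_vol standard deviation of the yearly log-growth innovations.
#' @param phe_rho AR(1) coefficient of the log-growth deviations; near 1
#'   makes the regressor highly persistent.
#' @param noise_sd residual standard deviation of the outcome equation
#'   (ignored when `arch_a1 > 0`; then `arch_a0`/`arch_a1` set the scale).
#' @param arch_a0,arch_a1 ARCH(1) conditional-variance parameters;
#'   `arch_a1 = 0` means homoskedastic noise.
#' @param maternal_start,child_start initial outcome levels (deaths per
#'   100,000 and per 1,000 respectively).
#' @param n_years panel length in years.
#' @param start_year first calendar year.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return A list of class `dgp_config`.
#' @export
dgp_config <- function(alpha = 0.85, beta = -0.05, theta = -0.02,
                       gamma = 0.85, phe_start = 100, phe_drift = 0.03,
                       phe_vol = 0.04, phe_rho = 0.95, noise_sd = 0.03,
                       arch_a0 = 0, arch_a1 = 0,
                       maternal_start = 300, child_start = 80,
                       n_years = 26, start_year = 1995, seed = NULL) {
  cfg <- list(alpha = alpha, beta = beta, theta = theta, gamma = gamma,
              phe_start = phe_start, phe_drift = phe_drift,
              phe_vol = phe_vol, phe_rho = phe_rho, noise_sd = noise_sd,
              arch_a0 = arch_a0, arch_a1 = arch_a1,
              maternal_start = maternal_start, child_start = child_start,
              n_years = as.integer(n_years),
              start_year = as.integer(start_year), seed = seed)
  validate_dgp_config(cfg)
  structure(cfg, class = "dgp_config")
}

validate_dgp_config <- function(cfg) {
  if (cfg$phe_start <= 0) stop("phe_start must be > 0", call. = FALSE)
  if (cfg$maternal_start <= 0 || cfg$child_start <= 0)
    stop("outcome start levels must be > 0", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$phe_vol < 0) stop("phe_vol must be >= 0", call. = FALSE)
  if (cfg$arch_a1 < 0 || cfg$arch_a1 >= 1)
    stop("arch_a1 must lie in [0, 1)", call. = FALSE)
  if (cfg$arch_a1 > 0 && cfg$arch_a0 <= 0)
    stop("arch_a0 must be > 0 when arch_a1 > 0", call. = FALSE)
  if (abs(cfg$gamma) > 1)
    stop("gamma must satisfy |gamma| <= 1", call. = FALSE)
  if (cfg$n_years < 2) stop("n_years must be >= 2", call. = FALSE)
  invisible(cfg)
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# simulate one log-outcome path given the log-PHE path
simulate_log_outcome <- function(cfg, log_phe, start_level) {
  n <- cfg$n_years
  ly <- numeric(n)
  ly[1] <- log(start_level)
  dlx <- c(NA, diff(log_phe))
  eps <- numeric(n)
  if (cfg$arch_a1 > 0) {
    z <- stats::rnorm(n)
    sigma2 <- cfg$arch_a0 / (1 - cfg$arch_a1)  # unconditional start
    for (t in 2:n) {
      sigma2 <- cfg$arch_a0 + cfg$arch_a1 * eps[t - 1]^2
      eps[t] <- sqrt(sigma2) * z[t]
    }
  } else if (cfg$noise_sd > 0) {
    eps[2:n] <- stats::rnorm(n - 1, sd = cfg$noise_sd)
  }
  for (t in 2:n) {
    ly[t] <- cfg$alpha + cfg$beta * log_phe[t - 1] +
      cfg$theta * dlx[t] + cfg$gamma * ly[t - 1] + eps[t]
  }
  ly
}

#' Generate a synthetic country panel
#'
#' Draws one panel from the data-generating process described in
#' [dgp_config()]. The same dynamic equation is applied to the maternal and
#' the under-five series, each with its own independent noise stream; with
#' `noise_sd = 0` and `arch_a1 = 0` both outcome series satisfy the
#' recursion exactly. Fully reproducible from `seed`.
#'
#' @param config a [dgp_config()].
#' @param country name attached to the generated panel.
#' @return A [country_panel].
#' @examples
#' p <- generate_panel(dgp_config(seed = 1))
#' nrow(p)  # 26
#' @export
generate_panel <- function(config, country = "synthetic") {
  stopifnot(inherits(config, "dgp_config"))
  validate_dgp_config(config)
  if (config$gamma == 1)
    warning("gamma = 1: outcome recursion has a unit root", call. = FALSE)
  with_seed(config$seed, {
    n <- config$n_years
    v <- if (config$phe_vol > 0) stats::rnorm(n - 1, sd = config$phe_vol)
         else numeric(n - 1)
    u <- numeric(n - 1)
    for (t in seq_len(n - 1))
      u[t] <- if (t == 1) v[1] else config$phe_rho * u[t - 1] + v[t]
    log_phe <- log(config$phe_start) + c(0, cumsum(config$phe_drift + u))
    lm_mat <- simulate_log_outcome(config, log_phe, config$maternal_start)
    lm_chd <- simulate_log_outcome(config, log_phe, config$child_start)
    country_panel(country,
                  years = config$start_year + 0:(n - 1),
                  phe = exp(log_phe),
                  maternal = exp(lm_mat),
                  child = exp(lm_chd))
  })
}

#' Generate a collection of independent synthetic panels
#'
#' Per-country seeds are derived deterministically from `master_seed` (one
#' draw of `sample.int` per country under the master stream), so the whole
#' collection is reproducible while the countries' noise streams differ.
#'
#' @param configs list of [dgp_config()] objects, or a single config to be
#'   reused for every country.
#' @param names unique country names, same length as `configs` (or any
#'   length when a single config is given).
#' @param master_seed integer master seed.
#' @return Named list of [country_panel] objects.
#' @export
generate_multicountry <- function(configs, names, master_seed = 1L) {
  if (inherits(configs, "dgp_config"))
    configs <- rep(list(configs), length(names))
  if (length(configs) != length(names))
    stop("configs and names must have equal length", call. = FALSE)
  if (anyDuplicated(names))
    stop("duplicate country names", call. = FALSE)
  if (length(configs) == 0L) return(stats::setNames(list(), character()))
  seeds <- with_seed(master_seed,
                     sample.int(.Machine$integer.max, length(configs)))
  panels <- mapply(function(cfg, nm, sd) {
    cfg$seed <- sd
    generate_panel(cfg, country = nm)
  }, configs, names, seeds, SIMPLIFY = FALSE)
  stats::setNames(panels, names)
}
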