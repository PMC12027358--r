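# shared fixtures: small deterministic panels built in code

# noise-free panel whose outcome satisfies the dynamic recursion exactly
zero_noise_panel <- function(alpha = 0.5, beta = -0.05, theta = -0.01,
                             gamma = 0.6, n_years = 26, seed = 101,
                             country = "oracleland") {
  generate_panel(dgp_config(alpha = alpha, beta = beta, theta = theta,
                            gamma = gamma, noise_sd = 0, phe_vol = 0.05,
                            n_years = n_years, seed = seed),
                 country = country)
}

# default stochastic panel: homoskedastic noise
noisy_panel <- function(seed = 202, noise_sd = 0.03, n_years = 26, ...) {
  generate_panel(dgp_config(noise_sd = noise_sd, n_years = n_years,
                            seed = seed, ...))
}

# independent hand-rolled iteration of the forecast recursion
hand_recursion <- function(alpha, beta, theta, gamma, base_phe,
                           base_outcome, g, n_steps) {
  lx <- log(base_phe)
  ly <- log(base_outcome)
  out <- numeric(n_steps)
  for (h in seq_len(n_steps)) {
    ly <- alpha + beta * lx + theta * log(1 + g) + gamma * ly
    lx <- lx + log(1 + g)
    out[h] <- exp(ly)
  }
  out
}

# a predictive_fit stub with chosen coefficients (for degenerate cases the
# estimator itself refuses, e.g. beta = theta = gamma = 0)
fit_stub <- function(alpha, beta, theta, gamma,
                     outcome = "maternal", country = "stubland") {
  structure(list(alpha = alpha, beta = beta, theta = theta, gamma = gamma,
                 coefficients = c(alpha, beta, theta, gamma),
                 estimator = "OLS", outcome = outcome, country = country),
            class = "predictive_fit")
}
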