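test_that("OLS interpolates a noise-free panel exactly", {
  p <- zero_noise_panel(alpha = 0.5, beta = -0.05, theta = -0.01,
                        gamma = 0.6)
  for (oc in c("maternal", "child")) {
    f <- fit_ols(p, oc)
    expect_equal(unname(f$coefficients), c(0.5, -0.05, -0.01, 0.6),
                 tolerance = 1e-9)
    expect_lt(max(abs(f$residuals)), 1e-10)
    expect_equal(f$n_obs, nrow(p) - 1L)
    expect_true(all(f$cond_sd == 1))
  }
})

test_that("a constant outcome yields a degenerate-design error", {
  set.seed(61)
  p <- country_panel("flatland", 2000:2015,
                     phe = exp(cumsum(c(3, runif(15, 0.02, 0.15)))),
                     maternal = rep(200, 16),
                     child = seq(80, 65, -1) * exp(rnorm(16, 0, 0.02)))
  expect_error(fit_ols(p, "maternal"), "degenerate design")
  expect_s3_class(fit_ols(p, "child"), "predictive_fit")
})

test_that("short panels are refused for estimation", {
  p <- country_panel("tiny", 2000:2007, phe = exp(rnorm(8, 3, .1)),
                     maternal = exp(rnorm(8, 5, .1)),
                     child = exp(rnorm(8, 4, .1)))
  expect_error(fit_ols(p, "maternal"), "too short")
})

test_that("variance fit collapses to the sample variance without ARCH structure", {
  # squared residuals anti-correlated at lag 1: the lag coefficient is
  # negative and gets clipped to zero
  e <- rep(c(3, 1), 10)
  cv <- fit_conditional_variance(e)
  expect_equal(cv$a, 0)
  expect_true(all(cv$variances == mean(e^2)))
})

test_that("fitted conditional variances respect the floor", {
  set.seed(8)
  for (i in 1:20) {
    e <- rnorm(30, sd = runif(1, 0.001, 2))
    cv <- fit_conditional_variance(e, sig_level = 1)
    expect_true(all(cv$variances >= cv$floor))
    expect_equal(cv$floor, (0.01 * sd(e))^2)
  }
  expect_error(fit_conditional_variance(rnorm(5)), "insufficient")
})

test_that("ARCH(1) parameters are recovered from a long simulated series", {
  # oracle: direct simulation of sigma2_t = a0 + a1 e_{t-1}^2, n = 5000;
  # bounds frozen at +-4 sampling SDs of the least-squares estimator
  # (a1 is biased slightly downward at this n; bounds account for it)
  set.seed(44)
  a0 <- 0.1; a1 <- 0.5; n <- 5000
  e <- numeric(n)
  for (t in 2:n) e[t] <- sqrt(a0 + a1 * e[t - 1]^2) * rnorm(1)
  cv <- fit_conditional_variance(e)
  expect_gt(cv$a, 0.10); expect_lt(cv$a, 0.78)
  expect_gt(cv$a0, 0.05); expect_lt(cv$a0, 0.18)
})

test_that("FQGLS equals OLS when the fitted weights are constant", {
  p <- noisy_panel(seed = 11)
  fo <- fit_ols(p, "maternal")
  fq <- fit_fqgls(p, "maternal")
  if (length(unique(fq$cond_sd)) == 1L) {
    expect_equal(fq$coefficients, fo$coefficients, tolerance = 1e-8)
  }
  # and multiplying all weights by a constant never changes coefficients
  d <- phemort:::build_design(p, "maternal")
  s <- seq(0.5, 2, length.out = length(d$y))
  b1 <- phemort:::ls_core(d$X / s, d$y / s)$coef
  b2 <- phemort:::ls_core(d$X / (3.7 * s), d$y / (3.7 * s))$coef
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("FQGLS weighted residuals satisfy the normal equations", {
  p <- generate_panel(dgp_config(arch_a0 = 0.002, arch_a1 = 0.6,
                                 n_years = 60, seed = 21))
  fq <- fit_fqgls(p, "maternal")
  d <- phemort:::build_design(p, "maternal")
  w <- 1 / fq$cond_sd
  rw <- (d$y - as.numeric(d$X %*% fq$coefficients)) * w
  ortho <- t(d$X * w) %*% rw
  expect_lt(max(abs(ortho)) / max(abs(d$y)), 1e-8)
  expect_equal(fq$estimator, "FQGLS")
})

test_that("FQGLS is no less efficient than OLS under ARCH noise", {
  set.seed(9)
  betas <- t(replicate(500, {
    p <- generate_panel(dgp_config(arch_a0 = 0.001, arch_a1 = 0.6,
                                   n_years = 151,
                                   seed = sample.int(2^31 - 1, 1)))
    c(suppressWarnings(fit_fqgls(p, "maternal"))$beta,
      fit_ols(p, "maternal")$beta)
  }))
  expect_lte(var(betas[, 1]), var(betas[, 2]))
})

test_that("FQGLS falls back to OLS when the variance step is degenerate", {
  p <- noisy_panel(seed = 17)
  # ARCH order larger than the residual series can support
  expect_warning(f <- fit_fqgls(p, "maternal", order = 25),
                 "falling back to OLS")
  expect_equal(f$estimator, "OLS")
  expect_equal(f$coefficients, fit_ols(p, "maternal")$coefficients)
})

test_that("the relationship screen follows the sign of beta and flags low-mortality countries", {
  p <- noisy_panel(seed = 33)
  f <- fit_ols(p, "maternal")
  f$beta <- 0.0343          # published positive case
  s <- screen_relationship(f, p)
  expect_true(s$nil)
  expect_equal(s$beta_sign, "non-negative")
  f$beta <- -0.0364         # published negative case
  s <- screen_relationship(f, p)
  expect_false(s$nil)
  expect_false(s$already_below_targets)  # default panel starts high

  set.seed(62)
  low <- country_panel("lowland", 1995:2020,
                       phe = exp(cumsum(c(5, runif(25, 0.01, 0.08)))),
                       maternal = seq(60, 40, length.out = 26) *
                         exp(rnorm(26, 0, 0.02)),
                       child = seq(20, 14, length.out = 26) *
                         exp(rnorm(26, 0, 0.02)))
  sl <- screen_relationship(fit_ols(low, "child"), low)
  expect_true(sl$already_below_targets)
})
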