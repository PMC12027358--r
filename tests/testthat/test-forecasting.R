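test_that("window splitting follows floor arithmetic and guards short training", {
  p <- noisy_panel()  # 26 years
  sw <- split_window(p, 0.75)
  expect_equal(nrow(sw$train), 19)
  expect_equal(nrow(sw$eval), 7)
  expect_equal(sw$eval$year[1], max(sw$train$year) + 1L)
  sw2 <- split_window(p, 0.5)
  expect_equal(nrow(sw2$train), 13)
  expect_equal(nrow(sw2$eval), 13)
  expect_error(split_window(p, 0.2), "too short")
})

test_that("in-sample fitted levels reproduce a noise-free panel and track a low-noise one", {
  p0 <- zero_noise_panel()
  f0 <- fit_ols(p0, "maternal")
  isf <- in_sample_fitted(f0, p0)
  expect_equal(nrow(isf), nrow(p0) - 1L)
  expect_equal(isf$fitted, isf$actual, tolerance = 1e-9)

  p1 <- noisy_panel(seed = 55, noise_sd = 0.02)
  isf1 <- in_sample_fitted(fit_ols(p1, "maternal"), p1)
  expect_gt(cor(isf1$actual, isf1$fitted), 0.95)

  expect_error(in_sample_fitted(f0, p1), "does not match")
})

test_that("scenario paths compound exactly", {
  expect_equal(unname(scenario_path(100, scenario_spec(0.10, 2020, 2023))),
               c(110, 121, 133.1), tolerance = 1e-12)
  expect_equal(unname(scenario_path(100, scenario_spec(0, 2020, 2025))),
               rep(100, 5))
  expect_equal(unname(scenario_path(100, scenario_spec(0.30, 2020, 2030)))[10],
               100 * 1.3^10, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:25) {
    g <- runif(1, -0.5, 0.5); base <- runif(1, 1, 1000)
    path <- scenario_path(base, scenario_spec(g, 2020, 2030))
    h <- seq_along(path)
    expect_lt(max(abs(path / (base * (1 + g)^h) - 1)), 1e-12)
  }
  expect_error(scenario_spec(-1), "exceed -1")
  expect_error(scenario_spec(0.1, 2030, 2020), "end_year")
})

test_that("the scenario recursion matches an independent hand iteration", {
  set.seed(14)
  cases <- list(c(0.5, -0.05, -0.01, 0.6),
                c(0.2, -0.10, 0.02, 0.9),
                c(1.1, -0.02, -0.05, 0.3),
                c(-0.3, -0.08, 0.00, 0.75))
  for (cc in cases) {
    p <- zero_noise_panel(cc[1], cc[2], cc[3], cc[4],
                          seed = sample.int(1e6, 1))
    f <- fit_ols(p, "maternal")
    fp <- recursive_forecast(f, 100, 300, scenario_spec(0.1, 2020, 2030))
    oracle <- hand_recursion(f$alpha, f$beta, f$theta, f$gamma,
                             100, 300, 0.1, 10)
    expect_equal(unname(fp$mortality), oracle, tolerance = 1e-10)
    expect_equal(fp$mortality_rounded, round(fp$mortality))
  }
})

test_that("a static fit forecasts the constant exp(alpha)", {
  f <- fit_stub(alpha = log(250), beta = 0, theta = 0, gamma = 0)
  fp <- recursive_forecast(f, 100, 300, scenario_spec(0.1, 2020, 2030),
                           nil = FALSE)
  expect_equal(unname(fp$mortality), rep(250, 10), tolerance = 1e-12)
})

test_that("forecasts decline in the growth rate when beta < 0, theta <= 0, gamma in [0,1)", {
  p <- zero_noise_panel(alpha = 0.5, beta = -0.05, theta = -0.01,
                        gamma = 0.6)
  f <- fit_ols(p, "maternal")
  paths <- lapply(c(0.1, 0.2, 0.3), function(g)
    recursive_forecast(f, 100, 300, scenario_spec(g, 2020, 2030))$mortality)
  expect_true(all(paths[[2]] <= paths[[1]]))
  expect_true(all(paths[[3]] <= paths[[2]]))
})

test_that("log forecasts approach the analytic linear asymptote", {
  f <- fit_stub(alpha = 0.5, beta = -0.05, theta = -0.01, gamma = 0.6)
  g <- 0.2
  fp <- recursive_forecast(f, 100, 300, scenario_spec(g, 2020, 2320),
                           nil = FALSE)
  slopes <- diff(log(unname(fp$mortality)))
  expect_equal(slopes[length(slopes)],
               f$beta * log(1 + g) / (1 - f$gamma), tolerance = 1e-6)
})

test_that("mortality forecasts are invariant to rescaling the PHE units", {
  p <- noisy_panel(seed = 77)
  sp <- scenario_spec(0.2, max(p$year), 2030)
  f1 <- fit_ols(p, "maternal")
  m1 <- recursive_forecast(f1, p$phe[nrow(p)], p$maternal[nrow(p)],
                           sp)$mortality
  p2 <- country_panel(panel_country(p), p$year, p$phe * 1000,
                      p$maternal, p$child)
  f2 <- fit_ols(p2, "maternal")
  m2 <- recursive_forecast(f2, p2$phe[nrow(p2)], p2$maternal[nrow(p2)],
                           sp)$mortality
  expect_equal(m1, m2, tolerance = 1e-8)
})

test_that("nil fits yield Nil paths without mortality forecasts", {
  f <- fit_stub(alpha = 0.5, beta = 0.02, theta = -0.01, gamma = 0.6)
  fp <- recursive_forecast(f, 100, 300, scenario_spec(0.1, 2020, 2030))
  expect_true(fp$nil)
  expect_null(fp$mortality)
  expect_equal(length(fp$phe_path), 10)
})

test_that("recursive one-step evaluation uses expanding windows of observed data", {
  p0 <- zero_noise_panel()
  oos <- recursive_oos_evaluation(p0, "maternal", 0.75, "OLS")
  expect_equal(nrow(oos), 7)
  expect_equal(oos$year, tail(p0$year, 7))
  expect_equal(oos$forecast, oos$actual, tolerance = 1e-8)

  # first forecast coincides with a fixed fit on the initial training set
  p <- noisy_panel(seed = 91)
  oos1 <- recursive_oos_evaluation(p, "maternal", 0.75, "OLS")
  f19 <- fit_ols(split_window(p, 0.75)$train, "maternal")
  i <- 20
  lhat <- f19$alpha + f19$beta * log(p$phe[i - 1]) +
    f19$theta * (log(p$phe[i]) - log(p$phe[i - 1])) +
    f19$gamma * log(p$maternal[i - 1])
  expect_equal(oos1$forecast[1], exp(lhat), tolerance = 1e-12)
})
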