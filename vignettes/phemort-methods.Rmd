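---
title: "Methods: dynamic mortality forecasting under health-expenditure scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic mortality forecasting under health-expenditure scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phemort)
```

## The model

phemort fits, per country and per mortality outcome, the dynamic double-log
predictive regression

$$\log Y_t \;=\; \alpha + \beta \log X_{t-1} + \theta\, \Delta \log X_t
  + \gamma \log Y_{t-1} + \varepsilon_t ,$$

where $Y_t$ is the mortality level (maternal deaths per 100,000 or
under-five deaths per 1,000 live births) and $X_t$ is public health
expenditure (PHE) per capita in constant currency units. $\beta$ carries the
substantive hypothesis — negative when higher spending predicts lower
mortality; $\gamma$ absorbs the strong persistence of mortality series and
$\theta$ the contemporaneous expenditure impulse. Natural logarithms are
used throughout (the convention when no base is stated), so coefficients
are elasticities and the model is invariant to the currency unit of $X$: a
rescaling of PHE moves only the fitted intercept, and end-to-end
fit-plus-forecast output is unchanged (this is asserted in the test suite).

Annual series of 26 years (1995–2020 in the motivating application) leave
25 usable observations after the lag; the estimation functions refuse
panels shorter than 10 years.

## Estimation: OLS and the two-step FQGLS

`fit_ols()` estimates the equation by least squares. Mortality and
expenditure series are persistent — near-unit-root regressors with possibly
conditionally heteroskedastic errors — which motivates a Feasible
Quasi-Generalised Least Squares (FQGLS) estimator: consistent,
asymptotically normal, and robust to heteroskedasticity. The published
account names the estimator without formulas, so the implementation is the
package's own design, the standard two-step scheme:

1. fit by OLS and keep the residuals $\hat\varepsilon_t$;
2. fit an ARCH(1) conditional-variance model
   $\sigma_t^2 = a_0 + a_1 \hat\varepsilon_{t-1}^2$ by least squares of the
   squared residuals on their lag;
3. divide every regression row — response and all regressors, including the
   intercept column — by $\hat\sigma_t$;
4. re-estimate by least squares on the weighted system.

Two guard rails shape step 2 (`fit_conditional_variance()`):

* **Non-negativity and significance screening.** Lag coefficients are
  clipped at zero, and by default retained only when positive and one-sided
  significant at the 5% level. Any data-driven weighting scheme would
  otherwise pick up spurious ARCH structure in small homoskedastic samples
  and perturb the coefficients for no gain; with the screen, series without
  detectable ARCH structure get constant weights, which cancel exactly, so
  FQGLS degrades gracefully to OLS — the behaviour the estimator's
  robustness promise implies. `sig_level = 1` disables the screen for users
  who want pure clipped least squares.
* **A variance floor** of $(0.01 \times \mathrm{sd}(\hat\varepsilon))^2$
  prevents near-zero fitted variances from exploding the weights.

If the variance step fails outright (too few residuals for the requested
order, non-finite variances), `fit_fqgls()` falls back to OLS with a
warning rather than aborting a multi-country run.

A country's relationship is screened on the *sign of the point estimate*
alone: $\hat\beta \ge 0$ marks the country `Nil` — higher PHE is not
projected to reduce its mortality and no scenario forecast is issued —
regardless of significance. This is the rule that reproduces which
countries appear as "Nil" in the published forecast tables given the signs
in the published regression summary. Separately, a country whose observed
maternal series stayed below 70 and child series below 25 throughout the
sample is flagged `already_below_targets` (the screening rule under which
Mauritius was excluded from the motivating analysis, leaving 24 countries);
the flag checks both series because the exclusion rationale cites both.

## Forecast validation

`split_window()` takes the first $\lfloor f \cdot T \rfloor$ years as
training (canonical $f$ = 0.50 and 0.75). `recursive_oos_evaluation()`
uses an expanding (recursive) window: for each evaluation year the model is
re-estimated on all data up to the preceding year and a one-step-ahead
forecast is formed with the *observed* PHE values — scenario paths play no
role in validation, which separates model assessment from counterfactual
projection.

Forecast quality is summarised by the mean squared error on mortality
*levels* (the quantities of interest, after identical exponential
back-transforms for every model), and model comparison by the
Campbell–Thompson out-of-sample $R^2$,

$$\mathrm{OOS}\ R^2 \;=\; 1 - \widehat{\mathrm{MSE}}_2 /
  \widehat{\mathrm{MSE}}_1 ,$$

positive when the unrestricted predictive model beats the restricted
benchmark. Two benchmarks are provided:

* **Historical average** — the geometric mean of the training levels
  (the mean of the logs, exponentiated), recomputed each recursive step.
  The geometric rather than arithmetic mean keeps the benchmark in the same
  log space as the predictive model, so MSEs compare like with like.
* **ARIMA** — fitted to the log levels with the order selected by AIC over
  the small grid $p \in \{0,1,2\}$, $d \in \{0,1\}$, $q \in \{0,1\}$ (the
  published account names ARIMA without an order; this is the smallest
  defensible search). AIC values across different $d$ condition on
  slightly different effective samples — a standard, accepted approximation
  at this series length. Non-convergent or zero-variance fits fall back to
  the (0,1,0) random walk (forecast = last level) with a warning.

No formal critical values for the Campbell–Thompson statistic are computed;
only its sign and magnitude are interpreted.

## Scenario projection

A scenario assumes PHE grows by a fixed proportion $g$ every year from the
last observed level, compounding multiplicatively:
$X_{2020+h} = X_{2020}(1+g)^h$, so $\Delta \log X_t = \log(1+g)$ is
constant (this matches the iterated "multiply the preceding level again"
construction of the published scenarios; canonical $g$ = 0.10, 0.20, 0.30).
`recursive_forecast()` then iterates the fitted equation from the observed
2020 mortality level, feeding each forecast back as the lagged outcome:

$$\log \hat Y_t = \hat\alpha + \hat\beta \log X_{t-1}
  + \hat\theta \log(1+g) + \hat\gamma \log \hat Y_{t-1}.$$

With $\hat\gamma \in (0,1)$ the log forecast approaches a linear-in-time
asymptote with slope $\hat\beta \log(1+g)/(1-\hat\gamma)$ per year, and
with $\hat\beta < 0$, $\hat\theta \le 0$ forecasts are monotonically
non-increasing in $g$ — the qualitative pattern across the 10/20/30%
published tables; both properties are asserted in the tests.

Scenario forecasts use the full-sample fit seeded at the 2020 observation
(the 75%-split evaluation validates that specification; whether the
published tables used the training fit or the full-sample fit is not
stated, and both routes are available here). Levels are recovered by plain
exponentiation — no smearing or log-normal bias correction, since the
published tables apply none — and report tables round to the nearest
integer (R's round-half-even, immaterial at these magnitudes).

## SDG assessment

`classify_sdg()` compares integer-rounded 2030 forecasts with the SDG
targets (70 maternal / 25 child). The comparison is *inclusive* (`<=`):
the published 20%-scenario child table lists countries printed exactly at
25 as achievers, which fixes the convention. `Nil` countries carry
`achieved = NA` — never counted as achieving or failing — and the
percent-achieved denominator is the non-Nil set (22 of the 24 analysed
countries in the child tables), the convention that reproduces the
published "about 60%" headline (13/22 = 59.1%). Packaged fixtures
transcribe the published tables with `Nil` as an explicit sentinel, never
zero or silently missing, because `Nil` is a statement about the sign of a
relationship, not absent data.

## The synthetic data generator

Real WHO expenditure panels require an external download, so
`generate_panel()` draws panels with the statistical structure the analysis
assumes, making every stage testable offline:

* **PHE**: $\log X_t = \log X_{t-1} + d + u_t$ with
  $u_t = \rho u_{t-1} + v_t$, $v_t \sim N(0, \mathrm{phe\_vol}^2)$ and
  $\rho$ defaulting to 0.95 — a drifting, near-unit-root expenditure level,
  exactly the persistence the FQGLS estimator is designed for. Defaults
  (start 100, drift 0.03, vol 0.04) give a realistic slow real-terms growth
  path.
* **Mortality**: both outcome series follow the dynamic equation above with
  independent noise streams. Defaults $\alpha=0.85$, $\beta=-0.05$,
  $\theta=-0.02$, $\gamma=0.85$ reflect the strong year-to-year persistence
  of observed mortality and a modest negative expenditure elasticity, and
  place the conditional steady state near 60 at the default expenditure
  level, so default panels decline gently over the sample rather than
  collapsing; starting levels (300 per 100,000 maternal, 80 per 1,000
  child) are typical mid-1990s magnitudes for the region studied. The dynamic
  equation needs an initial outcome level, which the published model
  specification does not parameterise; it is exposed as
  `maternal_start` / `child_start`.
* **Noise**: i.i.d. normal, or ARCH(1) when `arch_a1 > 0`. Normality is a
  package choice — the published account never states an error
  distribution — and ARCH(1) is the simplest form that exercises the
  heteroskedasticity robustness target; richer forms would slot into the
  same interface.
* **Reproducibility**: each panel is a pure function of its config's seed
  (the caller's RNG stream is saved and restored);
  `generate_multicountry()` derives per-country sub-seeds from one master
  seed so that collections are reproducible while countries' streams
  differ.

What the generator does *not* emulate: measurement revisions and rounding
in reported mortality, structural breaks (epidemics, conflict), policy
feedback from mortality to expenditure, and cross-country correlation.
Passing tests therefore demonstrate that the estimator and forecaster
recover the model they assume — not that the model is true of any actual
country.

## Numerical choices and degenerate inputs

* Rank-deficient designs (e.g. a constant outcome, or perfectly
  exponential PHE making $\Delta\log X$ constant) raise a
  degenerate-design error rather than returning NA coefficients.
* The variance floor, ARCH significance screen and OLS fallback are
  described above; all are deterministic.
* Zero restricted-model MSE with nonzero unrestricted MSE makes the
  out-of-sample $R^2$ undefined and raises an error; both zero returns 0.
* Pipeline runs (`run_pipeline()`) skip countries whose fit fails, with a
  warning, and continue.

## Simulation sizes

The test suite and the acceptance script size their Monte-Carlo checks so
each completes in seconds on one core while leaving Monte-Carlo error well
below the asserted effects: 2,000 panels for the drift moment check, 500
replicates for parameter recovery (T = 200 and 50) and the FQGLS/OLS
efficiency comparison (T = 150), 300 replicates for the ARCH signature
check, and 200 panels each for the strong-signal and null out-of-sample
comparisons.

## Known limitations

* Estimates of $\gamma$ carry the classical $O(1/T)$ small-sample bias of
  least squares with a lagged dependent variable (about $-0.001$ at
  $T = 200$ under the generator defaults); it vanishes as $T$ grows but is
  detectable in large Monte-Carlo runs.
* Point forecasts only: no prediction intervals or stochastic simulation
  of forecast uncertainty.
* The published regression coefficients and forecast tables derive from
  WHO data not shipped here; they enter as transcribed fixtures validating
  the SDG-assessment stage, not as quantities the estimation stage
  reproduces.
* Unit handling is the user's: PHE is treated as per-capita constant
  currency; no deflation or PPP conversion is performed.
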