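Package: phemort
Title: Forecasting Maternal and Child Mortality Under Public Health
    Expenditure Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-country dynamic log-log predictive models linking maternal
    and under-five mortality to public health expenditure (PHE) per capita,
    estimated by ordinary least squares and by a two-step Feasible
    Quasi-Generalised Least Squares (FQGLS) estimator robust to conditional
    heteroskedasticity. Provides recursive expanding-window out-of-sample
    forecast evaluation against historical-average and ARIMA benchmarks
    (mean squared error and the Campbell-Thompson out-of-sample R-squared),
    compounded PHE growth scenario projection of mortality to 2030, and
    classification of countries against the Sustainable Development Goal
    targets of 70 maternal deaths per 100,000 and 25 under-five deaths per
    1,000 live births. Includes a synthetic panel generator with persistent
    expenditure dynamics and optional ARCH(1) noise so the full pipeline is
    testable without external data, and packaged fixtures of published
    forecast tables for the SDG assessment stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
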