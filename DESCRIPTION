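Package: metnorm
Title: Meteorological Normalization of Particulate Matter Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De-weathering analysis of daily particulate matter (PM1, PM2.5,
    PM10) mass concentrations. Fits random-forest and gradient-boosted tree
    regressions of PM on meteorological and temporal predictors, tuned by
    Gaussian-process Bayesian optimization over temporal-block
    cross-validation, then removes short-term weather influence by repeatedly
    permuting all predictors except the Julian-day trend variable, predicting,
    and averaging the draws into a normalized series. Includes period
    comparison (pre-lockdown, lockdown, post-lockdown windows), one-way ANOVA
    with year as the categorical factor, PM-ratio screening for
    out-of-ordinary events, and a seeded synthetic generator of daily
    meteorology and PM with known trend, seasonality, intervention and dust
    spikes so that effect recovery is measurable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    ranger,
    stats,
    utils,
    xgboost,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
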