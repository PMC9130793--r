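Package: metaplast
Title: Metabolic Plasticity, Growth and Respirometry Under Variable Food Supply
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the time course of resting-metabolic-rate (RMR)
    plasticity in fishes under changing food supply. Provides (i) processing of
    closed-chamber respirometry oxygen traces into mass-specific oxygen uptake
    (MO2), (ii) an analytic simulator of rate-limited, clamped RMR plasticity
    coupled to food-level-dependent linear growth, (iii) a seeded generator of
    synthetic crossover feeding experiments with individual variation,
    measurement noise and injected outliers, and (iv) the longitudinal
    inference pipeline: robust time-series outlier cleaning, food-level
    specific weekly slope estimation (transparent two-stage estimator and a
    linear mixed model with AR(1) residuals), penalized-spline trajectory
    smoothing with GCV, Welch group comparisons and weekly food-intake
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    nlme,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
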