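Package: tspower
Title: Precision and Power Planning for Time-Series Regression of Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form approximations for the standard error of exposure
    coefficients in quasi-Poisson time-series regressions of daily event
    counts, and the planning quantities that follow from a standard error:
    confidence-interval width, power, smallest detectable coefficient and
    required number of events. Covers single-series designs and multi-series
    (multi-city) designs analysed by fixed- or random-effects meta-analysis
    of series-specific coefficients, with heterogeneity entered as tau or
    I-squared. Includes a profiler that estimates the "usable" exposure
    standard deviation SD(x|z) by residualising an exposure series on the
    covariate design a final analysis would use (seasonal spline,
    day-of-week, extra covariates), and a Monte-Carlo validation engine that
    checks the approximations against fitted quasi-Poisson regressions and
    two-stage meta-analyses on synthetic series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    jsonlite
Config/testthat/edition: 3
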