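Package: tempmort
Title: Two-Stage Distributed-Lag Analysis of Temperature and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-stage time-series design used in multi-city
    studies of ambient temperature and mortality. Fits city-specific
    conditional Poisson models with a natural-cubic-spline temperature x lag
    cross-basis (distributed lag non-linear models), pools the lag-cumulated
    exposure-response curves across cities with multivariate random-effects
    meta-regression (REML) and best linear unbiased predictions, and derives
    the headline risk summaries: minimum mortality temperature, relative
    risks at tail percentiles, extreme-temperature slopes, and excess death
    fractions with Monte Carlo confidence intervals. Includes a synthetic
    multi-city data generator with a known lagged exposure-response surface
    for validation, Ward clustering of cities by their temperature
    distributions, and grouped conditional Poisson fits for sparse
    cause-specific outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
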