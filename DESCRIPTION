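Package: tempburden
Title: Two-Stage Distributed-Lag Analysis of Temperature-Mortality
    Associations and Attributable Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the mortality burden of non-optimal
    ambient temperature from multi-location daily time series. Implements
    per-location quasi-Poisson regression with distributed-lag non-linear
    models (cross-basis of exposure and lag splines), reduction to the
    overall cumulative exposure-response association, multivariate
    random-effects meta-regression across locations with best linear
    unbiased predictions, minimum-mortality-temperature estimation, and
    backward attribution of deaths to cold and heat with Monte-Carlo
    empirical confidence intervals. Includes a synthetic-data generator
    with a known exposure-lag-response surface so the full pipeline can be
    validated against recoverable truth, and helpers to derive daily
    series from hourly temperature and dewpoint records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    splines,
    stats,
    utils
Suggests:
    metafor,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
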