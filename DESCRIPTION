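Package: longevhaz
Title: Non-Parametric Estimation of the Risk of Dying at Extreme Old Ages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the age trajectory of the mortality hazard
    above age 105 from individual-level longevity records, as collected in
    registries such as the International Database on Longevity. Records may be
    fully observed, right-censored, or interval-censored to calendar years
    (US-style). The estimator is fully non-parametric: deaths and person-years
    of exposure are tallied on a grid of short age intervals and converted to
    central death rates, with uncertainty assessed through simulation-based
    empirical confidence intervals. Interval-censored records are handled by
    bounds-based multiple imputation of exact birth dates. A synthetic-cohort
    generator with known ground-truth hazards (constant plateau, Gompertz,
    piecewise-constant) supports validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
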