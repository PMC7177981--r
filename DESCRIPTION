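Package: codatime
Title: Compositional Data Analysis for 24-Hour Time-Use Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 24-hour time-use data as compositions on the
    simplex: closure, perturbation and powering; centered, additive and pivot
    (isometric) logratio transforms with exact inverses; compositional
    descriptives (geometric-mean center, variation array, Aitchison distance,
    logratio-normal predictive regions, ternary coordinates); multiplicative
    replacement of rounded zeros; linear regression of health outcomes on
    pivot coordinates with a global composition test; compositional
    isotemporal-substitution estimates with confidence intervals,
    dose-response curves and ternary response surfaces; and a calibrated
    synthetic-cohort generator plus a command-line interface so complete
    analyses can be run and tested without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
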