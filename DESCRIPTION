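Package: windkesselrc
Title: Fast Windkessel Resistance and Compliance Estimation from Blood
    Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates vascular resistance (R) and compliance (C) of a
    lumped-parameter (Windkessel) vessel segment directly from systolic and
    diastolic blood pressure, by tabulating the closed-form pressure solution
    of the vessel's second-order dynamics over an admissible (R, C) grid and
    intersecting the iso-contours of the measured pressures.  On top of the
    estimator it provides dose-effect (Emax) curve fitting for
    angiotensin-converting enzyme inhibitor therapy, simulation of
    post-treatment blood pressure, a composite cardiac integrated index (CII)
    for scoring seven-component hemodynamic profiles, and a synthetic-cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
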