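Package: dielstab
Title: Temporal-Stability Analysis and Correction of Sampling-Time Bias in
    Soil CO2 Efflux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and correcting the bias introduced by the
    time of day at which manual chamber measurements of soil respiration (Rs)
    are taken. Implements the temporal-stability framework: per-hour relative
    differences (RD) of hourly fluxes against the 24-hour mean, multi-campaign
    mean relative difference (MRD) and its standard deviation (SDMRD), hour
    ranking and optimal-sampling-window selection, and a division-based
    correction factor for non-optimally timed monitoring series. Includes
    seasonal and hydrological-year budget aggregation with percent-difference
    reporting, JZS Bayes-factor t-tests and Bayesian linear regressions for
    downstream comparisons, and a Q10-driven diel-cycle simulator that
    provides ground truth for validating every step without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
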