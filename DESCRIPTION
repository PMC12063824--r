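Package: chlorovar
Title: Timescales and Drivers of Chlorophyll Variability from Estuarine
    Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing phytoplankton (chlorophyll a) variability
    in long-residence-time estuaries from in-situ sonde and monitoring-program
    records. Provides quality control of high-frequency (15-minute) sonde data
    with gap interpolation and daily averaging, multiplicative decomposition of
    monthly chlorophyll series into annual, seasonal and residual timescale
    components, threshold-based detection and merging of bloom events on daily
    series, per-event selection of environmental driver models (all-subsets
    ordinary least squares ranked by small-sample corrected AIC, with
    cross-correlation screening of lagged predictors, collinearity pruning and
    backward elimination), and seeded Monte Carlo simulation of reduced
    monitoring frequencies. Includes a synthetic-data generator that emulates
    the statistical structure of such records with full ground-truth ledgers
    for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
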