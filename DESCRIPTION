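Package: concindex
Title: Concentration Index and Decomposition Analysis of Health-Service
    Utilization Equity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures socioeconomic inequality in the utilization of health
    services from person-wave survey data.  Computes weighted fractional
    ranks, concentration curves, and the concentration index (twice the
    covariance between the outcome and the fractional economic rank, divided
    by the outcome mean) with delta-method standard errors; decomposes the
    index into per-covariate contributions through probit average marginal
    effects (Wagstaff-type decomposition) and derives the horizontal
    inequity index by removing the need-variable contributions; fits
    stratified logistic models with survey-year fixed effects for odds-ratio
    tables; and ships a synthetic survey-panel generator with a
    numeric-integration oracle for the true index, so every stage of the
    pipeline can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
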