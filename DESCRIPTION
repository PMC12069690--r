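Package: accessmap
Title: Survey-Based Mapping of Inequities in Access to HIV Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing geographic and demographic
    inequities in access to antiretroviral therapy from population-based HIV
    survey data. Provides design-based estimation of HIV prevalence and
    treatment coverage with stratified delete-one-PSU jackknife variance and
    design-based F-tests; logistic cumulative-distribution-function models of
    interval-censored self-reported travel times with bootstrap confidence
    bands and age-adjusted odds-ratio models; ordinary kriging of cluster-level
    prevalence into epidemic surface prevalence maps with leave-one-out
    cross-validation; density-of-infection rasters (people with HIV per square
    kilometre) by raster multiplication with gridded population; and epidemic
    concentration curves with a minimum-density-for-coverage solver. A
    synthetic-country generator (population grid, spatially autocorrelated
    prevalence field, two-stage stratified cluster survey with design and
    jackknife replicate weights, geomasked cluster coordinates) supplies data
    with known ground truth so every stage is testable without restricted
    survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
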