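Package: seastrat
Title: Design-Based Stratified Estimation for Towed-Video Benthic Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the abundance of benthic epifauna (developed
    for the European flat oyster, Ostrea edulis) from stratified random
    towed-video surveys. Site tables of counts per filmed area are combined
    with the areal extents of depth strata into design-based population
    totals with standard errors (classical stratified-sampling estimators),
    and into derived stock metrics: occurrence frequencies, living/dead
    ratios, cumulative density concentration curves and the share of the
    population in bed densities, detection-efficiency corrected totals,
    biomass, and exploitation rates. A synthetic-survey generator produces
    patchy, zero-inflated oyster populations over a stratified frame and
    simulates the towed-video observation process with imperfect detection,
    so the whole pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
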