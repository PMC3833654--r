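Package: homacut
Title: HOMA-IR Cut-Points and Metabolic Syndrome Classification in
    Pediatric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for insulin-resistance screening analyses in
    school-age cohorts: computation of the homeostasis model assessment
    of insulin resistance (HOMA-IR), classification of the metabolic
    syndrome (MS) under a modified ATP III definition with
    cohort-derived waist and blood-pressure percentile thresholds,
    derivation of reference-population 95th-percentile HOMA-IR
    cut-offs stratified by sex, age and pubertal (Tanner) stage,
    ROC-based optimal cut-point selection by the Youden index and the
    distance to (0,1), quintile odds-ratio analysis of MS and its
    components, and prevalence tables of insulin resistance across
    weight-status groups. Includes a seeded synthetic-cohort generator
    with a latent adiposity/insulin-resistance factor so the full
    pipeline is testable without access to any study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
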