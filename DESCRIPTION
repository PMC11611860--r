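Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal mining on spontaneous
    adverse event reports in the FDA Adverse Event Reporting System
    (FAERS) quarterly ASCII format: table ingestion, case-version
    deduplication, primary-suspect cohort extraction, MedDRA preferred
    term (PT) and system organ class (SOC) contingency tables, and four
    disproportionality statistics -- the reporting odds ratio (ROR), the
    proportional reporting ratio (PRR) with its chi-squared companion,
    the Bayesian confidence propagation neural network information
    component (BCPNN IC), and the empirical Bayes geometric mean (EBGM)
    -- with conventional screening thresholds and EBGM05 ranking.  A
    seeded synthetic-report generator with planted drug-event signals,
    duplicate case versions, and configurable demographic marginals
    supports end-to-end testing without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
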