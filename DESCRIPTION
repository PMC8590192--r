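Package: periomop
Title: Perioperative Anesthesia Data in the OMOP Common Data Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes perioperative data - anesthesia information
    management system (AIMS) exports and hospital-discharge (PMSI-like)
    records - into an OMOP common data model subset extended with two
    tables, PERIOD and FEATURE, for secondarily computed data. Provides a
    concept registry with local-to-standard semantic mapping and coverage
    reporting, a relational CDM store with integrity checking and
    delimited-text round-tripping, threshold-episode detection on
    30-second intraoperative signals (hypotension burden: episode counts,
    time and area under threshold), period and feature derivation, eight
    audit/research queries over operating-room visits, four dashboard
    indicator sets, and a seeded synthetic source-data generator with
    recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
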