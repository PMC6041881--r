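Package: cohortvault
Title: Catalogue-Driven Management, Quality Profiling and Pseudonymised
    Extraction of Longitudinal Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale data-management platform for longitudinal tabular
    health data. A metadata catalogue (column descriptions, validation rules,
    governance tiers, lookups, issues) drives an audited RAW-STAGING-LIVE load
    pipeline with cleaning, schema-drift tolerance, primary-key upsert and
    bitemporal archiving of superseded rows; data-quality reports and summary
    aggregates; a composable cohort builder with set algebra over filter trees;
    and a disclosure-controlled extraction pipeline that substitutes stable
    per-project release identifiers, enforces column governance, blocks
    blacklisted columns and scans free text for checksum-valid patient
    identifiers before emitting an auditable release bundle. A seeded
    synthetic-data generator produces longitudinal clinical worlds with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    ggplot2,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
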