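Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case/non-case disproportionality analysis pipeline for
    spontaneous adverse-event reporting data in the FAERS quarterly ASCII
    layout: record deduplication and aberrant-date cleaning, drug-lexicon
    matching, grouping of MedDRA preferred terms into narrow Standardized
    MedDRA Query (SMQ) categories, shrinkage-corrected information component
    (IC) and reporting odds ratio (ROR) estimation with 95% intervals and a
    three-part signal rule, cumulative time-trend and stratified analyses,
    time-to-onset and outcome-severity summaries, and a synthetic
    spontaneous-report generator with closed-form ground truth so every
    stage is testable without access to the full reporting database.
License: MIT
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
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
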