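Package: fusionburden
Title: Consensus Gene-Fusion Calling, Fusion Burden and Survival Analysis
    for RNA-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Harmonizes chimeric-transcript calls from three RNA-seq fusion
    callers into one canonical table, applies a support / read-through /
    blacklist filter cascade with two-of-three caller consensus, builds a
    cohort-level fusion catalog with known-fusion annotation,
    private/recurrent classification and per-chromosome inter/intra
    distributions, quantifies per-sample fusion burden, selects a survival
    cutpoint by quantile scanning with Kaplan-Meier and log-rank inference,
    scores per-sample immune gene-set enrichment, and ships a fully seeded
    synthetic-cohort generator (caller files, clinical table, expression
    matrix, truth file) so the whole pipeline is testable without
    controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
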