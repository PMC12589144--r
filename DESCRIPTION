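Package: hlhscreen
Title: Case Finding for Haemophagocytic Lymphohistiocytosis with the
    HScore, Revised HLH-2004 Criteria and Ferritin Screening Rules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for retrospective case finding of secondary
    haemophagocytic lymphohistiocytosis (sHLH) in hyperferritinaemic
    cohorts. Implements the HScore points system and the revised
    HLH-2004 diagnostic criteria with explicit missing-data and
    assay-ceiling (censored ferritin) policies, evaluates simple
    ferritin/fever/platelet screening rules against a configurable
    reference standard (confusion matrices, sensitivity, specificity,
    Youden index), and provides the replication statistics used in such
    audits: the uncorrected Pearson chi-squared test of independence on
    2x2 tables, the Mann-Whitney U test with a tie-corrected normal
    approximation, and population-standard-deviation z confidence
    intervals for a mean. A synthetic cohort generator with latent
    case labels makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
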