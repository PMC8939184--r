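Package: cohorttrend
Title: Temporal Expression Trend Calling, Survival Stratification and Hub-Gene
    Selection in Diagnosis-Year-Binned Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses bulk expression cohorts binned by calendar year of
    diagnosis. Calls genes whose bin-mean expression rises (or falls) in at
    least k of the B-1 consecutive bin comparisons, ranks them by last-versus-
    first-bin log2 fold-change, intersects the called lists with oncogene,
    tumor-suppressor and lincRNA catalogs, runs hypergeometric (Fisher or
    EASE-score) gene-set over-representation against GMT pathway collections,
    stratifies overall survival at a maximally selected log-rank cutpoint per
    gene, and applies a four-part hub-gene filter combining trend shape,
    fold-change and survival significance. A synthetic cohort generator with
    planted monotone drifts, expression-dependent exponential survival and
    enriched pathway sets provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
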