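Package: cebpameth
Title: CEBPA Promoter Methylation Scoring and Cohort Analysis for Normal-Karyotype AML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CpG methylation in the CEBPA promoter from bisulfite-Sanger
    C/T peak heights, applies the 15 percent call threshold, computes the
    distal-promoter methylation ratio with mean-threshold dichotomization into
    negative/low/high classes, simulates methylation-specific PCR (MSP) for the
    core promoter in silico, and runs the downstream cohort statistics
    (contingency tests, ratio comparisons, expression-methylation rank
    correlation) and survival analyses (Kaplan-Meier, log-rank, Cox
    proportional hazards, subgroup analyses) used to characterize
    cytogenetically normal AML. Includes a seeded synthetic-cohort generator so
    the full pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
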