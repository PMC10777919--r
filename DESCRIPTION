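Package: tmef
Title: Tumor Methylated Fraction Estimation from Cell-Free DNA Methylation Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers short cancer-indicative differentially methylated
    regions (DMRs) from fragment-level bisulfite methylation calls, annotates
    them with background noise, prevalence and pull-down efficiency, and
    infers a tissue-free tumor methylated fraction (TMeF) for plasma
    cell-free DNA samples from per-region fragment counts using a binomial
    mixture likelihood aggregated over a log-spaced tumor-fraction grid.
    Includes hematopoietic-lineage DMR filtering, Bayesian per-region
    prevalence estimation, an in-silico dilution laboratory for
    limit-of-quantification titrations with coverage correction, log-log
    scaling fits of TMeF against primary tumor size, and a synthetic cohort
    generator so every stage runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
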