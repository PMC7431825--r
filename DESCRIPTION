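Package: rdnaclock
Title: Age-Dependent Ribosomal DNA Methylation in Mammalian Sperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of age-dependent DNA methylation of ribosomal DNA (rDNA)
    and other repeats in mammalian sperm. Implements single-molecule deep
    bisulfite sequencing (DBS) amplicon processing with bisulfite-aware
    alignment, per-read conversion quality control, A/G allele splitting and
    an epimutation-rate statistic; cohort-level correlation statistics with
    confounder adjustment and cross-species life-span scaling; and a sperm
    rDNA methylation clock (penalized-regression age predictor with KNN
    imputation and cross-validated penalty selection). A synthetic-data
    module generates bisulfite reads and methylation cohorts with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
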