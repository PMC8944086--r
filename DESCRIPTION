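Package: methage
Title: DNA Methylation Age Acceleration, Entropy and Outcome Analysis for
    Glioblastoma-Style 450k Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for Illumina 450k-style DNA
    methylation cohorts of IDH-wild-type glioblastoma: probe filtering and
    beta/M-value handling, empirical-Bayes batch aggregation, epigenetic-clock
    DNAm age and age acceleration, stratified methylation Shannon entropy,
    methylome-wide differential and functional methylation scans with
    hypergeometric gene-set enrichment, copy-number segmentation and CDKN2A
    homozygous-deletion calling, methylation-based purity and MGMT-STP27
    classification, and multivariate/outcome statistics (PCA, permutation
    MANOVA, variation partitioning, HC3 Wald tests, interaction Cox models,
    Cochran-Mantel-Haenszel). A seeded synthetic-cohort generator with a
    ground-truth record makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    vegan,
    sandwich,
    mclust,
    sva,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
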