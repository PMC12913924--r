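Package: igeprs
Title: Leave-One-Group-Out Polygenic Risk Scores for Total IgE and
    Asthma Phenotype Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs a polygenic risk score (PRS) for total serum
    immunoglobulin E (IgE) from genotype data using a leave-one-group-out
    (LOGO) cross-validation design: per-fold genome-wide association,
    linkage-disequilibrium clumping with p-value thresholding, scoring of
    all individuals with every fold model, and inverse-variance
    meta-analytic combination into a single standardized score. Around the
    score the package provides genotype quality control (call rate, minor
    allele frequency, exact Hardy-Weinberg test, heterozygosity outliers,
    KING-robust kinship), genotype principal components, model-based
    two-step clustering of asthma phenotypes with BIC-selected cluster
    number, nearest-centroid classification of new cases, a battery of
    group-comparison statistics, and a seedable synthetic cohort generator
    so the full pipeline is testable without access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
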