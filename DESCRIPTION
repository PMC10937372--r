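Package: metaxes
Title: Multi-Ancestry GWAS Meta-Regression, Mechanistic Clustering and
    Partitioned Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for dissecting heterogeneity in multi-ancestry
    genome-wide association studies of complex disease. Builds axes of
    genetic variation from allele-frequency distances between studies,
    aggregates allelic effects by meta-regression with a partition of
    Cochran's Q into ancestry-correlated and residual heterogeneity,
    clumps significant variants into independent signals and loci,
    clusters index variants on sample-size-corrected cardiometabolic
    z-score profiles by k-means with iterative imputation of missing
    values, tests cell-type open-chromatin enrichment with Firth
    bias-reduced logistic regression, and evaluates cluster-partitioned
    polygenic scores against clinical outcomes with random-effects
    meta-analysis across ancestry groups. A synthetic-data generator
    emulates every input so the full pipeline runs and is tested without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    cluster,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    metafor,
    withr
Config/testthat/edition: 3
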