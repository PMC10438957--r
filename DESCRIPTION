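Package: peakcoloc
Title: Threshold-Free Collocation Statistics for Genomic Interval Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the base-level collocation of two sets of genomic
    intervals (e.g. ChIP-seq or ATAC-seq peaks) with six threshold-free
    statistics: the collocation coefficient, Jaccard, Sorensen-Dice and
    Szymkiewicz-Simpson coefficients, and (normalized) pointwise mutual
    information. Provides non-parametric bootstrap confidence intervals,
    a one-query-versus-many-database scan that standardizes each metric to
    Z-scores, combines them into a single ranking statistic and flags
    3-standard-deviation outliers, the conventional threshold-and-count
    baseline for comparison, and generators for synthetic BED fixtures with
    controlled overlap structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    withr,
    generics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
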