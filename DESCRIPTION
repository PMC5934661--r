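Package: iwscore
Title: Integrative Weighted Scoring of Noncoding Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised integration of multiple per-variant noncoding
    functional scores into a single integrative weighted score (IW-score).
    Weights are the lead eigenvector of the pairwise-complete correlation
    matrix of the constituent scoring systems; missing scores are completed
    by expectation-maximization multiple imputation with bootstrap;
    query scores are rescaled onto the training scale and assigned
    upper-tail p-values against a shifted-lognormal (or empirical) null.
    Includes workflow presets for known and novel variants, benchmarking
    statistics (ROC/AUC with bootstrap confidence intervals, Wilcoxon
    rank-sum tests, Wilkinson combined p-values), detection of recurrently
    mutated noncoding regions, and a synthetic-data generator with the
    block-correlated two-class structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
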