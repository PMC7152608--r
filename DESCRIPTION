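Package: seedcoex
Title: Temporal and Genetic Co-Expression Analysis of Seed Development
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for time-course 3' tag RNA-seq of
    developing seed across a diversity panel: count-matrix quality control
    with size-factor normalisation and PCA outlier-cluster removal,
    negative-binomial differential expression between adjacent sampling
    times with a genotype-by-time interaction screen, discrete temporal
    co-expression (TCoE) pattern coding over {u, d, 0} with permutation
    nulls of inter-interval independence, genetic co-expression (GCoE)
    subclustering of pattern sets with PC1 eigengene heritability under a
    genomic relationship matrix, a permutation Mahalanobis test on cluster
    sizes, and metabolite-module association with permutation comparison.
    A synthetic-data generator with known truth makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    lme4,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
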