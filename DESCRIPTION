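Package: immunoscape
Title: Immune Tumor-Microenvironment Profiling from NanoString nCounter
    Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for immuno-oncology gene
    expression panels counted on the NanoString nCounter platform.
    Reads RCC lane files or raw count tables, performs control-probe and
    housekeeping-gene normalization with data-driven housekeeper
    selection, computes marker-gene abundance scores for 14 immune cell
    populations together with a total tumor-infiltrating-lymphocyte
    score and a Manhattan "immunological distance", clusters tumors into
    immune-hot and immune-cold groups, and runs nonparametric
    differential analyses (Kruskal-Wallis omnibus, Wilcoxon post hoc,
    Benjamini-Hochberg FDR control) on cell scores and genes, including
    gene-set decompositions and Spearman correlation panels.  A
    negative-binomial cohort simulator with planted immune-composition
    effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
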