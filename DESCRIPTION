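Package: lfqstats
Title: Downstream Statistical Analysis of Label-Free Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imports protein quantification tables from common proteomics
    search engines (MaxQuant, DIA-NN, FragPipe, Spectronaut, AlphaPept) and
    the mzTab exchange format into a single dataset object with an
    append-only preprocessing provenance log; provides contaminant removal,
    completeness filtering, log transformation, normalization
    (median-centering, quantile, z-score) and imputation (mean, median,
    k-nearest-neighbour, iterative tree-ensemble); runs per-protein
    differential expression (Welch and pooled t-tests, one-way ANOVA,
    ANCOVA, permutation-based significance analysis of microarrays with
    automatic fudge-factor tuning), Benjamini-Hochberg adjustment,
    hypergeometric over-representation analysis, principal component
    analysis and hierarchical clustering; computes plot-ready volcano,
    heatmap, PCA and dendrogram data with deterministic SVG export; and
    benchmarks preprocessing pipelines on synthetic spike-in data by ROC
    AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
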