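Package: screenSL
Title: Dual-Layer CRISPR Screen Analysis for Chemoresistance Synthetic
    Lethality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of pooled CRISPR-Cas9 screens for chemoresistance
    target discovery in triple-negative breast cancer models: pooled-screen
    sequencing quality control (mapping ratio, missed guides, Gini index,
    replicate correlations, PCA), gene essentiality beta scores with
    permutation p-values and re-sensitizer selection from genome-wide
    screens, dual-knockout synthetic-lethality scoring (Horlbeck, median
    and sgRNA-derived scores with background normalization, and a
    rank-aggregation statistic) with top-decile consensus calling and
    SL-network hub extraction, and a three-analysis cell-line
    representativeness framework (DEG co-clustering, top-variable-gene
    Spearman ranking, ssGSEA pathway similarity). Negative-binomial screen
    and transcriptome-cohort simulators with planted ground truth make the
    whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: CRISPR, PooledScreens, QualityControl, GeneExpression, Software
RoxygenNote: 7.3.3
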