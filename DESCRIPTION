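Package: rsstages
Title: Stage-Wise Random-Set Pathway Enrichment for Tumor Progression
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pathway-level analysis of multi-stage tumor transcriptomes
    using the Random-Set (RS) enrichment statistic: the mean rank of a
    gene set's two-sample t-statistics, standardized by the exact
    mean and variance of the mean of scores drawn without replacement
    from the array. Significance is assessed by phenotype-label
    permutation. The package reads GCT/CLS/GMT files, simulates
    expression data with planted enriched sets, runs per-stage
    enrichment contrasts with up/down direction calls, builds
    cross-stage trajectory and Venn-partition tables, and provides a
    weighted Kolmogorov-Smirnov (GSEA-style) enrichment score,
    Fisher-exact list-overlap statistics, and clustering/PCA
    diagnostics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
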