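Package: esProfiler
Title: Effect-Size Profiling and Cross-Species Cluster Linkage for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch-effect-robust analysis of small-sample, multi-species
    single-cell RNA-seq experiments. Each cluster of each sample is
    characterised by a profile of Glass rank biserial effect sizes (one
    coefficient per gene, cluster versus the rest of the sample); Spearman
    correlation between profiles links cell-type clusters across species
    without joint normalisation, and treatment-to-control effect-size
    ratios replace p-value based differential expression when only one
    sample per condition exists. Includes divisive intelligent k-means
    (DivIK) clustering with Gaussian-mixture feature filtration and
    gap-statistic model selection, a weighted Dice-Sorensen index for
    comparing clusterings, hypergeometric over-representation of selected
    genes, 10x-style matrix IO, and a seeded two-species negative-binomial
    simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    mclust,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
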