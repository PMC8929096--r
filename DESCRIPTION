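Package: scSaturation
Title: Sample-Size Saturation Analysis for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how the outcome of standard single-cell RNA-seq
    analyses depends on the number of cells profiled. Given (or simulating)
    a large pool of cells, the package draws a ladder of subsamples and
    tracks, per sample size, the number of significant principal components
    (JackStraw permutation test), the reliability of graph-based clustering
    against the full pool (Rand, Morey-Agresti, Hubert-Arabie, Fowlkes-
    Mallows and Jaccard pair-counting indices), the number of annotated
    cell types, the recovery of one-vs-rest differentially expressed genes
    with ROC classification power, and the stability of an MST-based
    pseudotime. Curves are summarised by a plateau rule into a recommended
    cell number, and a binomial planner estimates the cells needed to
    capture rare populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    igraph,
    irlba,
    RANN,
    matrixStats,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
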