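Package: scatacpipe
Title: Processing, Quality Control and Clustering of Single-Cell ATAC-seq Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for single-cell chromatin accessibility
    (scATAC-seq) fragment files: per-barcode quality metrics (FRiP, TSS
    enrichment, library complexity), cell calling by threshold filtering,
    a zero-inflated negative binomial mixture or knee-point detection,
    bin- and peak-level count matrix construction, a sliding-window Poisson
    peak caller with a cluster-then-call strategy for rare populations,
    TF-IDF and log-regression normalization, fast PCA with depth regression,
    SNN-Louvain clustering, Wilcoxon differential accessibility, motif
    deviation z-scores on GC-matched backgrounds, RPKM cluster tracks, and a
    simulation/benchmarking framework (binomial noise model, bulk
    subsampling, adjusted Rand index) with a pipeline driver and summary
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Matrix,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
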