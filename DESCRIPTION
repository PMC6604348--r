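Package: pollsort
Title: Cell Type Annotation for Single-Cell RNA-Seq by Marker-Gene Approval Voting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for clustering single-cell RNA-seq
    expression matrices and automatically labelling each cluster with a cell
    type. Cells are normalized, log-transformed and variance-filtered, then
    clustered agglomeratively on a principal-component projection, with the
    number of clusters selected from the stability (adjusted Rand index) curve
    of repeated mini-batch K-means partitions. Cluster labels are obtained by
    approval voting of marker genes over a user-supplied marker/cell-type
    database, with statistical significance assessed against a size-preserving
    random-cluster null model. Includes recursive sub-typing, a synthetic-data
    generator with planted ground truth, diagnostic figures, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rtsne,
    ggplot2,
    patchwork,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
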