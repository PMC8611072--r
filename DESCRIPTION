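Package: chronet
Title: Temporal Regulatory Module Inference from Chromatin Accessibility
    and Expression Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers sequential regulatory modules from dense differentiation
    time courses of chromatin accessibility (DNase I hypersensitive site
    densities) and gene expression. Calls developmentally regulated features
    by cubic-spline regression with a likelihood-ratio test, clusters
    temporal profiles, links distal DHSs to target genes by correlation
    within a genomic window, tests motif enrichment per temporal cluster,
    models each DHS's accessibility from the expression of motif-compatible
    transcription factors via elastic-net regression with per-cluster
    hyperparameter selection, resolves TFs and their target DHSs into
    sequential regulatory modules, and builds stage-specific TF-to-gene
    networks. A synthetic-data generator with planted regulatory structure
    supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    limma,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
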