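Package: splicecnn
Title: Convolutional Splice-Site Prediction with Synthetic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating convolutional neural network
    classifiers of eukaryotic splice sites (donor and acceptor) directly from
    genomic DNA. Includes a synthetic multi-exon gene simulator that plants
    canonical GT/AG boundary signals, branchpoint and polypyrimidine-tract
    motifs so the whole pipeline is testable without external data; dataset
    construction with false-positive, exonic and intronic negative sampling
    under balanced or unbalanced class ratios; one-hot sequence encoding; a
    small three-layer convolutional classifier trained with the Adamax
    optimiser; a five-metric evaluation and benchmark-aggregation harness; and
    gradient-weighted class activation (Grad-CAM) heatmaps for per-position
    interpretability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
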