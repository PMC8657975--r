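Package: scSCA
Title: Sparsely Connected Autoencoders for Single-Cell Omics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for interpreting single-cell RNA-seq and ATAC-seq data
    with sparsely connected autoencoders (SCA): masked autoencoders whose
    hidden nodes are interpretable metafeatures (transcription factors,
    miRNAs, or cell clusters). Provides cluster-level pseudo-bulk
    pseudo-replicates from repeated SCA runs, transcription-factor/miRNA
    metagene matrices by cumulative summation of hidden layers,
    cross-experiment cluster matching via Pearson similarity, a peak-to-gene
    activity matrix builder for scATAC-seq, standard single-cell
    preprocessing filters, and a zero-inflated negative-binomial simulator
    with planted regulatory modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    methods,
    fgsea,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
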