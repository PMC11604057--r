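Package: snpdemux
Title: SNP-Assisted Demultiplexing of Hashed Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hybrid demultiplexing of cell-hashing (hashtag oligo)
    single-cell RNA-seq experiments. Hashing counts are classified with a
    per-hashtag negative-binomial mixture model; high-confidence singlets
    are used to infer per-sample and sample-pair (doublet) SNP consensus
    profiles from sparse single-cell variant calls; negative, uncertain
    and doublet cells are then reassigned by nearest-centroid
    classification under a Jaccard distance adapted for missing data.
    Includes a count-level benchmark simulator (genotypes, dropout,
    call errors, negative-binomial hashing counts, doublets by barcode
    merging) and evaluation utilities (accuracy, precision/recall,
    adjusted Rand index, doublet accounting, within-group distance QC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    mclust,
    e1071,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
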