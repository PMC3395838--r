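Package: phyloFootprint
Title: Phylogenetic Footprinting of Transcription Factor Binding Sites
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts transcription factor binding sites (TFBS) by
    phylogenetic footprinting over multi-species promoter alignments.
    Position weight matrices from TRANSFAC, JASPAR, UNIPROBE or generic
    tabular files are converted to log2-odds form and calibrated against
    the exact background score distribution (column-wise convolution on a
    discretized score grid) to obtain per-matrix score thresholds at a
    target p-value. Promoter windows around transcription start sites are
    scanned in MAF alignment blocks, calling a site only when every
    required species exceeds the threshold at the same alignment columns.
    Predicted target sets are assessed by one-sided Fisher exact
    enrichment against annotation term collections, and the resulting
    term-by-matrix score matrix is mined for inclusion-maximal all-ones
    biclusters. A compartment-annotated mixed interaction graph (directed
    regulatory and undirected physical edges) can be built for any gene
    list, laid out with compartment-anchored forces inside nested
    cellular-component zones, filtered, expanded from an interaction
    compendium, and exported to SIF or GraphML. Deterministic synthetic
    generators with planted signal cover every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
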