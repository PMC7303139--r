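Package: hirumine
Title: Mining Anticoagulant Gene Families from Annotated Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Similarity-search screening of a predicted proteome against a
    panel of archetypal leech anticoagulants, with reciprocal-search
    orthology filtering, gene copy-number and tandem-array calling,
    pairwise conservation reports (shared-site similarity, cysteine
    conservation, indels) and clan-based orthology corroboration on
    unrooted gene trees. Includes affine-gap local and semi-global
    alignment with Karlin-Altschul bit scores and E-values, neighbor
    joining with bootstrap support, and a synthetic-data generator that
    plants divergent gene families (tandem arrays, conserved cysteine
    scaffolds, indels) with machine-readable truth tables so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
biocViews: SequenceMatching, Alignment, Phylogenetics, ComparativeGenomics
RoxygenNote: 7.3.3
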