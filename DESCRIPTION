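Package: repeatgraph
Title: Graph-Based Identification and Characterization of Repetitive DNA
    from Low-Pass Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies repetitive DNA families directly from
    unassembled low-pass whole-genome shotgun reads. All-to-all read overlaps
    are detected with a k-mer seeded Smith-Waterman aligner and admitted as
    edges of a read-similarity graph when they exceed 90 percent identity over
    at least 55 percent of the longer read. The graph is partitioned into
    clusters by greedy modularity agglomeration; each cluster is characterized
    by graph topology (density, diameter, maximal degree, internal
    modularity), quantified as a genome proportion, classified as
    satellite-like, ring-like or linear (dispersed-element-like), optionally
    annotated against a repeat library, and laid out in 3D with a
    force-directed algorithm. A built-in simulator generates genomes with
    tandem satellites, LTR-retrotransposon-like dispersed elements with
    deletion variants, rDNA-like arrays and single-copy background, with
    per-read truth labels, so the whole pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Biostrings,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
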