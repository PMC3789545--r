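Package: isomip
Title: Joint Transcript Identification and Quantification from
    Multi-Sample RNA-Seq by Mixed-Integer Optimization
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs and quantifies RNA transcripts simultaneously
    across multiple RNA-Seq samples. Builds a splicing graph of exonic
    segments from spliced alignments and/or annotation, attaches
    per-sample segment, intron and read-pair counts, and selects a small
    set of graph paths together with per-sample abundances by minimizing
    a negative-binomial read-count loss plus a row-sparsity penalty,
    solved by best-first branch-and-bound with convex piecewise-quadratic
    relaxations. Includes likelihood-ratio confidence scores for
    predicted transcripts, a two-sample differential transcript
    expression test, loss-guided multi-mapping read assignment, and a
    cassette-exon identifiability simulation quantifying when
    multi-sample data determine the transcript set uniquely.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    pracma,
    igraph,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
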