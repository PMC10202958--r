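Package: longbloom
Title: Reference-Free Transcriptome Assembly of Long Noisy RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A six-stage workflow for assembling transcripts from long,
    error-prone cDNA or direct-RNA sequencing reads without a reference
    genome: alignment-free error correction over a Bloom-filter de Bruijn
    graph, digital normalization to a minimal longest-reads set using
    randstrobe multiplicities tracked in a counting Bloom filter,
    depth-based read trimming and chimera splitting, overlap-graph unitig
    assembly with poly(A)-guided strand resolution and transitive
    reduction, pileup-consensus polishing, and greedy expression-guided
    transcript extraction. Includes a synthetic transcriptome and read
    simulator with ground truth, and transcript-level evaluation metrics
    (recall, false discovery rate, F1, redundancy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
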