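Package: seedwave
Title: Long-Read Seed-and-Extend Alignment with Wavefront Smith-Waterman
    and a Parallel Map-Reduce Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale long-read DNA aligner built from first principles:
    affine-gap Smith-Waterman local alignment with both a serial and a
    wavefront (anti-diagonal) matrix fill, FM-index/backward-search text
    indexes in which the reference prefix trie lives implicitly as suffix
    array intervals, a prefix-DAWG (suffix automaton) of the query, a
    seeding dynamic programme over the DAWG-by-trie product that yields
    seed interval pairs, and seed extension into full local alignments.
    Whole-sequence alignment runs under a small map-reduce engine that
    splits the reference into overlapping chunks, aligns query chunks in
    parallel map tasks, shuffle-sorts intermediate records by reference
    offset and reduces them to a nonredundant, nonoverlapping record set,
    with per-worker makespan accounting. Includes a deterministic
    synthetic read simulator with exact ground truth, FASTA input,
    TSV/SAM output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
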