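Package: cssstax
Title: Taxonomic Classification of DNA Sequences with Combined Sequence
    Similarity Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Nearest-neighbour taxonomic classifier for long and short DNA
    sequences.  Four heterogeneous similarity measures -- a seed-and-extend
    local alignment bit score, Euclidean distance and Jensen-Shannon
    divergence on canonical k-mer relative-abundance profiles, and a
    normalized compression distance -- are rescaled per query and averaged
    into a combined sequence similarity score (CSSS) used to assign each
    query the taxon of its nearest reference at a chosen taxonomic rank.
    The k-mer size and the subset of informative measures are tuned by
    leave-one-out cross-validation on the training references.  Includes an
    NCBI-style taxonomy flat-file parser, a persistent flat-file reference
    database, precision/recall evaluation, and a hierarchical sequence
    simulator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
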