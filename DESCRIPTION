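Package: evotsp
Title: Evolutionary Search for Weighted Top-Scoring Gene Pair Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rank-based classification of binary-labelled gene-expression
    profiles using ensembles of signed, weighted top-scoring gene pairs
    evolved by a genetic algorithm (EvoTSP). Includes the exhaustive
    Top-Scoring Pair (TSP), k-TSP and Top-Scoring Triplet (TST) baselines,
    a synthetic-data generator that plants rank-inversion signals with a
    controllable noise rate, a stratified cross-validation benchmark
    harness, and a command-line front end. All classifiers use only the
    within-sample ordering of expression values, so decisions are invariant
    to monotone per-sample normalisation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
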