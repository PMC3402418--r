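Package: rngtpatterns
Title: Pattern-Based Prediction and Identification for Random Number
    Generation Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of sequences produced in random number generation
    tasks, in which a subject repeatedly picks digits "at random". An
    edit-distance based affinity score quantifies how strongly a short
    pattern and its variants (insertions, deletions, substitutions,
    adjacent transpositions) are represented in a sequence; scoring all
    single-symbol extensions of the recent history yields a next-item
    predictor, a pairwise exact-hit prediction rate, and a triplet-based
    subject-identification procedure. Includes seeded synthetic-cohort
    generators (iid null, higher-order Markov chains with repetition
    avoidance, dominant-pattern weavers) for calibration and parameter
    recovery, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
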