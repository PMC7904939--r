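Package: simdta
Title: Similarity-Based Drug-Target Binding Affinity Prediction with a 2D
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts continuous drug-target binding affinities from chemical
    and sequence similarity alone. Drugs are compared by the Tanimoto
    coefficient over path-based topological fingerprints and protein targets
    by normalized Smith-Waterman local-alignment scores; the outer product of
    a drug's and a target's similarity vectors forms a two-dimensional grid
    that a small convolutional network regresses onto affinity. Includes the
    affinity-scale transforms (pKd, reversed KIBA scores), coverage-constrained
    k-fold cross-validation over observed pairs, the standard evaluation
    statistics for affinity regression (MSE, concordance index, modified
    r-squared, AUPR), candidate ranking against a fixed target, and a
    synthetic-data generator with a planted cluster-level affinity signal for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
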