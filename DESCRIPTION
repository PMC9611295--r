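Package: plinet
Title: Phase-Lag-Index Brain Functional Networks for Task-Switching EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multichannel EEG functional connectivity
    around task switching and mental fatigue. Decomposes recordings into the
    four classical rhythms (delta, theta, alpha, beta) with zero-phase
    filtering, estimates sliding-window phase lag index (PLI) connectivity,
    builds proportionally thresholded weighted networks and computes weighted
    characteristic path length, clustering coefficient, global and local
    efficiency across a sparsity sweep with area-under-curve aggregation,
    compares conditions by one-way ANOVA, ranks discriminative connections by
    consensus SVM recursive feature elimination, and classifies conditions
    with cross-validated SVM, random forest and k-nearest-neighbour models.
    Ships a synthetic coupled-oscillator cohort generator with planted,
    band-specific phase coupling so the full pipeline is testable without
    recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    igraph,
    e1071,
    randomForest,
    class,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
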