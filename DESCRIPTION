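Package: DNAbendR
Title: Deep Learning Prediction of Intrinsic DNA Cyclizability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the intrinsic cyclizability (C-score) of 50-bp DNA
    sequences from sequence alone using an inception-residual convolutional
    network followed by an LSTM layer, with reverse-complement averaging and
    linear detrending. Provides the full training stack (label
    standardization, 10-fold cross-validation with early stopping, rmsprop
    optimisation, detrend calibration), genome-scale sliding-window
    prediction with WIG/bedGraph track export, time-dependent Markov-chain
    sequence simulators, PWM motif simulation and scanning, dinucleotide
    periodicity and feature-anchored profile analytics, and a synthetic
    loop-seq-like library generator with a documented ground-truth
    bendability oracle for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
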