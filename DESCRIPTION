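Package: m6adeep
Title: Two-Stage Multi-Task Deep Learning for RNA N6-Methyladenosine Site
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts RNA N6-methyladenosine (m6A) sites from genomic
    sequence with a two-stage deep learning approach. Stage one is a
    multi-task convolutional/recurrent network that detects low-resolution
    m6A sites and simultaneously regresses an experiment-support score;
    stage two reuses the stage-one representation by transfer learning to
    discriminate base-resolution sites from low-resolution ones. Includes
    the complete dataset-construction pipeline (motif-centred window
    extraction, redundancy reduction, class balancing, stratified
    splitting, support normalisation), a hand-written seeded network
    engine (1-D convolution, group normalisation, BiLSTM, transformer
    encoder, multi-task loss, SGD), evaluation metrics and curves, and a
    synthetic-genome simulator with planted motifs so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
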