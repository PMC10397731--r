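Package: rhythmcode
Title: Brain Rhythm Code Features from Reassigned Time-Frequency EEG Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts multichannel EEG trials into dominant-rhythm symbol
    sequences via the reassigned smoothed pseudo-Wigner-Ville distribution
    (RSPWVD), extracts codon-like 3-base rhythm-code count features over the
    five canonical EEG bands (delta, theta, alpha, beta, gamma), scores every
    (channel, code) feature by leave-one-trial-out cross-validation with four
    classical classifiers (k-NN, RBF-SVM, LDA, multinomial logistic
    regression), and selects the single optimal channel-specific feature.
    Includes a seeded synthetic EEG generator with known dominant-band
    schedules and class-conditional planted code motifs so the entire
    pipeline is testable without access to licensed EEG corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
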