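Package: fnnbci
Title: Fuzzy Neural Network Classification of Multichannel EEG for
    Brain-Computer Interface Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing and classification pipeline for a
    six-command electroencephalography (EEG) brain-computer interface:
    overlapped windowing, per-channel centring, Hamming weighting and
    FFT magnitude features; information-gain feature ranking and
    selection; a six-layer Takagi-Sugeno-Kang fuzzy neural network
    trained by fuzzy c-means initialisation plus per-sample gradient
    descent with momentum and an adaptive learning rate; stratified
    10-fold cross-validation; a command-safety finite state machine
    with debouncing; and a synthetic 14-channel EEG generator so the
    whole pipeline runs without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
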