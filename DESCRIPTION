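Package: ieegnoise
Title: Artifact and Pathology Classification for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated identification of non-cerebral artifacts and
    pathological activity in multichannel intracranial EEG (iEEG).
    Three-second signal segments are transformed into a five-row feature
    matrix (a low-passed raw trace plus Hilbert power envelopes in four
    frequency bands spanning beta/gamma activity, ripples, fast ripples and
    very fast ripples) and classified with a one-dimensional convolutional
    neural network. A sliding-window detector summarises continuous
    recordings as channel-by-second artifact and pathology probability
    matrices, binarised at a 95% probability threshold. Includes transfer
    learning for adapting a generalized model to a new acquisition system,
    a synthetic iEEG generator for the four segment classes (physiological,
    pathological spike-with-HFO, power-line noise, broadband artifact),
    EDF and flat-array signal I/O, and confusion-matrix evaluation with
    recall, positive predictive value and F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
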