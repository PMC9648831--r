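Package: eegpref
Title: Subject-Independent EEG Preference Classification with
    Time-Frequency CNN Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for classifying like/dislike (valence)
    responses from multi-channel scalp EEG recorded while a tactile
    stimulus (a cosmetic cream) is applied. Implements Morlet-wavelet
    time-frequency decomposition with a fixed cycle count, sliding-window
    band-power features arranged as topology-preserving 5x5 electrode
    layout matrices and a 10x10 four-band merged matrix, per-subject
    two-class baseline correction, random oversampling for class balance,
    a family of seven small convolutional network classifiers trained
    with Adam, and leave-one-subject-out cross-validation with temporal
    median filtering of the predicted label sequence. A synthetic-EEG
    cohort generator with a 1/f background, alpha rhythm, 60 Hz line
    contamination, per-subject gain/offset domain shift, and a
    class-dependent band-power effect makes every stage testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
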