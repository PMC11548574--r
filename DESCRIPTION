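Package: ccan
Title: Cross-Attention Class Alignment for Cross-Subject EEG Decoding in
    Heterogeneous Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cross-subject motor-imagery EEG classification when
    source and target subjects differ in their label sets and, optionally,
    in channel montage and sampling rate.  Implements a cross-attention
    class alignment network: a two-pathway convolutional feature generator,
    a self- plus cross-attention cross-encoder, a class discriminator
    trained with a ratio loss that pulls corresponding-class features
    together while pushing non-corresponding classes apart, and a pair of
    averaged softmax classifiers, optimised with a two-step ADAM schedule.
    Includes Butterworth band-pass preprocessing, per-position z-score
    normalisation, enumeration and assembly of heterogeneous
    domain-adaptation scenarios, a class-conditional synthetic EEG
    generator for end-to-end testing, and a small reverse-mode automatic
    differentiation engine that powers training on plain CPUs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
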