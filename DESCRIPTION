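Package: mifatigue
Title: Motor-Imagery EEG Analysis of Fatigue, Rhythm Entropy, Phase
    Locking and Compact CNN Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for left/right-hand motor-imagery EEG with an
    emphasis on mental fatigue. Provides a synthetic session generator with
    planted event-related desynchronization (ERD), fatigue drift and
    parietal-frontal phase coupling; FIR band-pass filtering, resampling,
    epoching and baseline removal; Morlet time-frequency maps and ERD
    quantification with a pooled-variance t-test; a fused (theta+alpha)/beta
    and theta/beta fatigue index with correlation-based fatigue-sensitive
    channel selection; rhythm (spectral) entropy over frontal channels;
    phase-locking values between parietal and frontal channels; and a compact
    three-convolution CNN classifier with sliding-window augmentation,
    trained end to end in R. Results are returned as tibbles with ggplot2
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
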