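Package: gripnet
Title: Microstate and Brain-Network Decoding of Graded Hand-Clenching EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-trial EEG decoding pipeline for graded hand-clenching
    force and speed motor tasks. Implements preprocessing (common average
    reference, zero-phase FIR band-limiting, decimation, epoching, amplitude
    artifact rejection), EEG microstate analysis (global field power, GFP-peak
    topography clustering with a predictive-residual criterion for the number
    of maps, backfitting, and the duration/occurrence/coverage/amplitude
    parameters), directed spectral connectivity (multivariate autoregressive
    models and partial directed coherence, band-averaged into theta/alpha/beta
    networks), graph metrics (clustering coefficient and characteristic path
    length on density-thresholded networks), three classic feature families
    (ERD/ERS band energy, autoregressive power spectra, wavelet-packet node
    energies), and a classification protocol (extreme learning machine, SVM
    and shrinkage LDA under leave-one-subject-out and per-session
    cross-validation with permutation chance levels). A seeded synthetic EEG
    generator reproduces the statistical structure the pipeline assumes so
    every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
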