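Package: gpdcpipe
Title: Directed Connectivity Analysis Pipeline for Mobile Four-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for ambulatory four-channel dry-electrode
    EEG recorded together with head acceleration and per-electrode contact quality.
    Provides session file I/O, a synthetic-session generator with known ground-truth
    directed coupling, artifact rejection (notch and zero-phase Butterworth
    filtering, artifact subspace reconstruction, contact/voltage-jump/motion
    masking), generalized partial directed coherence from windowed multivariate
    autoregressive fits with Schwarz-criterion order selection, Thomson multitaper
    power spectral density, sample entropy, and variance-gated two-sample stage
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
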