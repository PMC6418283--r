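Package: ssvepmap
Title: Retinotopic and Topographic Analysis of Gaze-Restricted SSVEP Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of steady-state visual evoked potential
    (SSVEP) experiments performed under strict gaze restriction. Provides the
    concentric 46-flicker stimulus geometry, a forward simulator for
    multichannel EEG and eye-tracking sessions, fixation-ring trial gating,
    zero-phase notch and band-pass preprocessing, canonical-correlation
    scoring of epochs against harmonic reference signals, retinotopic
    response maps with central-versus-peripheral error-rate statistics,
    leave-one-out single-channel contribution topographies, and
    contralateral-effect scores with Kruskal-Wallis significance testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    interp,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
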