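Package: slowpred
Title: Recurrent-Network Prediction of Slow Hemodynamic Signal Fluctuations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the slow (<0.1 Hz) fluctuation of
    vessel-specific and region-of-interest resting-state fMRI signals.
    Provides spectral preprocessing (Welch power spectra,
    high-frequency power normalisation, zero-phase Butterworth
    band-pass filtering, resampling), a gated recurrent unit (GRU)
    forecaster with linear readout trained to predict the band-limited
    signal 10 s ahead, iterative amplitude adjusted Fourier transform
    (IAAFT) surrogate controls, an ARMAX baseline fitted by
    prediction-error minimisation, cross-correlation and Fisher-z
    scoring statistics, a prediction-score-based brain-state
    classifier (percentile grouping, seed correlation difference maps,
    intrinsic default-mode-network correlation, spectral reordering),
    vessel localisation on 2-D anatomical images, and seeded synthetic
    data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
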