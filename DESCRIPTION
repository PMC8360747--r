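Package: scalobp
Title: Blood-Pressure Classification from Photoplethysmography via
    Wavelet Scalograms and a Compact Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired photoplethysmography (PPG) and arterial
    blood-pressure (ABP) waveforms, labels blood-pressure categories from
    the ABP channel under the 2017 ACC/AHA hypertension thresholds,
    transforms PPG segments into time-frequency scalogram images through
    six continuous-wavelet bases (frequency B-spline, Shannon, complex
    Gaussian, Morlet, Mexican hat, Gaussian), and classifies normal
    versus abnormal blood pressure with a small convolutional neural
    network trained from scratch. Includes a direct-summation transform
    oracle, automated waveform quality control, deterministic dataset
    building with train/validation manifests, ROC evaluation, and a
    wavelet-by-segment-length grid comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
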