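Package: eegvigil
Title: EEG-Based Vigilance Detection with Wavelet Denoising and Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting drowsiness from scalp EEG recordings. A
    six-level Daubechies-5 wavelet decomposition removes low-frequency
    (blink) and high-frequency (electromyographic) interference by retaining
    the 4-64 Hz detail levels; per-second Hanning-windowed FFT power spectral
    densities yield theta/alpha/beta band-power features, averaged over a
    sliding time window; a soft-margin radial-basis-function support vector
    machine trained by sequential minimal optimization classifies each second
    as alert or drowsy. Includes a labelled synthetic EEG simulator with the
    occipital theta/alpha increase and beta decrease characteristic of sleep
    onset, block-contiguous cross-validation, grid search over the penalty
    and kernel-width parameters, accuracy/sensitivity/false-positive
    evaluation, and EDF/CSV input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    kernlab,
    knitr,
    optparse,
    quadprog,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
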