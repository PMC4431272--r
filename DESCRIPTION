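Package: emgmotion
Title: Surface EMG Feature Extraction and Upper-Limb Motion Classification
Version: 0.1.0
Authors@R: person("emgmotion", "developers", role = c("aut", "cre"),
    email = "emgmotion@example.org")
Description: A complete surface electromyography (sEMG) motion-recognition
    stack for eight upper-limb motions plus rest, recorded from six forearm
    and upper-arm muscles. Provides wavelet-packet preprocessing (Daubechies-2,
    level 4), four feature extractors (windowed RMS, Weight Peaks, windowed
    detrended fluctuation analysis, and a Hill-type muscular-model activation
    filter), two classifiers (a single-hidden-layer neural network and a
    support vector machine trained by sequential minimal optimization), a
    synthetic six-channel sEMG generator for desk-scale validation, and an
    end-to-end pipeline with a streaming evaluation loop and command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
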