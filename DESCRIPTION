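Package: emgswn
Title: Sliding-Window Normalization and Real-Time Motion Classification for Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration-free sliding-window normalization (SWN) for surface
    electromyography, together with the full myoelectric motion-classification
    pipeline built around it: causal Butterworth preprocessing with decimation,
    z-score and no-normalization baselines, five sliding-window feature
    extractors (mean absolute value, mean waveform length, difference RMS,
    short-time Fourier band power, stationary wavelet transform), two-link
    planar kinematics for rest/flexion/extension label generation, a balanced
    multinomial logistic-regression classifier, and OWN/OTHER inter-subject
    evaluation protocols with window-length and subject-count sweeps. A seeded
    multi-subject EMG and marker-position simulator provides cohorts with
    controlled inter-subject amplitude heterogeneity so the whole pipeline is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    nnet,
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
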