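Package: somnohr
Title: Heart-Rate-Based Automatic Sleep Staging from Single-Channel ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic sleep stage classification
    from heart rate: ECG signal-quality assessment via a sliding-window
    wavelet SNR index with epoch and recording rejection rules, R-peak
    detection to millisecond precision with spurious-beat correction and
    uniform RR tachogram resampling, per-epoch heart-rate-variability and
    ECG-derived-respiration features, a two-stage temporal-convolutional
    inception-residual network with hierarchical 4/3/2-level hypnogram
    output, an epoch/subject/cohort agreement-evaluation framework with
    covariate regressions, and dual-device hypnogram alignment. Ships a
    synthetic cohort generator (Markov hypnograms, stage-conditioned RR
    dynamics, parametric ECG waveforms) so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
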