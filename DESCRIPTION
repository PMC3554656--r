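Package: graspdetect
Title: Detection of Discrete Movement Events in Continuous Neural Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the times of discrete movement events (such as grasps)
    embedded in continuous multichannel electrocorticographic recordings.
    Implements causal feature extraction (a causal Savitzky-Golay low-pass
    component and normalized band-amplitude envelopes on a 4 Hz grid),
    regularized linear discriminant analysis posterior estimation, an online
    detection rule with bounded look-ahead and a refractory period, a
    tolerance-based evaluation framework with an analytic random-predictor
    baseline, blocked cross-validation with nested regularization selection,
    a frequency-band scan, and a synthetic session generator with
    event-locked signal structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
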