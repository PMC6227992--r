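Package: imikin
Title: Two-Person Imitation Kinematics: Preprocessing, Accuracy Scoring and
    Cluster-Length Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for two-person (actor-imitator) motion-tracking
    experiments with repetitive transcranial magnetic stimulation (rTMS).
    Provides artifact-robust kinematic preprocessing (electromagnetic spike
    removal, local-regression outlier repair, stimulation-artifact excision
    with spline interpolation, zero-phase Butterworth filtering), movement
    segmentation and peak kinematic parameters, imitation-accuracy scoring by
    correlation of amplitude-normalized velocity curves with Fisher's z,
    cluster-length permutation inference on sample-wise paired-t time-series,
    finger-thumb opposition task metrics (touch detection, inter-touch
    intervals, epoch speeds), fully-within repeated-measures ANOVA with
    Greenhouse-Geisser correction and Hedges' g for paired designs, and a
    synthetic-data generator producing actor-imitator trials with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
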