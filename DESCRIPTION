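Package: beatkit
Title: Beat-Level Fiducial Detection, Annotation and Evaluation for ECG and PPG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for annotating cardiac time series. Provides a
    block-streaming ECG R-peak detector (single-scale wavelet enhancement,
    quasi-peak-detector adaptive threshold, sub-sample quadratic refinement),
    a derivative-based PPG fiducial detector (foot, upstroke, systolic peak,
    shoulder, dicrotic notch, secondary peak), a three-mode annotation data
    model (instantaneous fiducials, named partitions, fixed-length labelled
    epochs), HDF5 workspace persistence, tolerance-matched detector
    evaluation (TP/FP/FN, F1, error rate), synthetic ECG/PPG generators with
    exact ground truth, and a five-code signal-quality labelling scheme with
    multi-annotator adjudication.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    rhdf5,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
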