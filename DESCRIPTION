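Package: remotion
Title: Contactless Emotion Recognition from FMCW Radar Vital Signs and Facial Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and processes frequency-modulated continuous-wave (FMCW)
    radar returns from a breathing, beating chest to recover respiration and
    heartbeat waveforms (moving-target indication, range FFT, phase extraction,
    variational mode decomposition), selects stable keyframes from face video by
    chi-square histogram distance, and classifies four emotional states
    (relaxed, happy, sad, angry) with a three-branch convolutional network fused
    into a gated recurrent unit. Includes a synthetic-trial generator with
    per-emotion physiological and facial presets, evaluation metrics,
    leave-one-out cross-validation, and person-dependent/-independent split
    protocols, so the whole pipeline is testable end-to-end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
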