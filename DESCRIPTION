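Package: fogcue
Title: Freezing-of-Gait Detection and Rhythmic Cueing from Ankle Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed detection of freezing-of-gait (FoG) episodes from 64 Hz
    triaxial ankle accelerometry and control of a rhythmic haptic cue. Provides
    a reader/writer for the DAPHNet plain-text dialect, 4 s sliding-window
    segmentation with 0.5 s steps, spectral and time-domain feature extraction
    including the Freezing Index (3-8 Hz freezing band over 0.5-3 Hz locomotion
    band power ratio), an RBF-kernel support vector machine with grid-searched
    hyperparameters, patient-independent (leave-one-patient-out) and
    patient-specific (repeated stratified split) evaluation with permutation
    feature importance, a streaming detector with ring buffer and cue-pattern
    hysteresis, a device packet codec, and a synthetic gait simulator that
    reproduces the stride/stance spectral structure of normal gait, 3-8 Hz
    trembling during FoG, and near-noise-floor standing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
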