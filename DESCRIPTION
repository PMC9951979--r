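Package: emg2gait
Title: Gait Event Detection from Surface EMG via Angular-Velocity Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs shank angular-velocity time series from temporally
    embedded surface-EMG envelopes using ordinary least-squares regression,
    extracts swing-peak, heel-contact and toe-off gait events from measured
    or reconstructed traces with a rule-based detector, and evaluates
    event timing and swing/stance segmentation under leave-one-patient-out
    cross-validation. Includes a synthetic gait-cohort generator producing
    paired raw EMG/IMU recordings with known ground-truth events so the
    full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
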