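Package: monohip
Title: Hip Range of Motion During Gait from a Single Thigh-Worn IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures sagittal hip range of motion (ROM) during gait from a
    single thigh-mounted inertial measurement unit (IMU). Provides zero-phase
    FIR filtering, cross-correlation synchronization with linear drift
    correction, gait-cycle segmentation and time normalization,
    sensor-to-segment functional calibration by principal component analysis
    of the gait angular velocity, per-cycle thigh ROM by strapdown integration
    and by complementary or Kalman sensor fusion, per-cycle signal features,
    a family of hip-ROM predictors (naive mean, simple and multiple linear
    regression, random forest, and recurrent neural networks), grouped and
    nested cross-validation, and Bland-Altman agreement statistics with a
    configurable limits-of-agreement validity criterion. A synthetic gait
    simulator generates ground-truth kinematics and matching IMU signals so
    the whole pipeline is testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ranger,
    rpart,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
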