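Package: pccr
Title: Binocular Pupil-Center/Corneal-Reflection Eye Tracking: Simulation,
    Detection, Calibration and Data Quality
Version: 0.1.0
Authors@R:
    person("pccr", "maintainers", email = "pccr@example.org", role = c("aut", "cre"))
Description: A tested software pipeline for binocular video eye tracking with
    the pupil-center/corneal-reflection (PC-CR) vector technique. Includes a
    model-eye video simulator with exact ground truth (optical geometry,
    pupil light responses, blinks, fixation at depth), threshold/center-of-mass
    detection of the dark pupil and the first Purkinje image, automated
    four-point linear calibration with a fixation-stability trigger, real-time
    style noise and blink analysis, regression-based correction of the
    pupil-decentration artifact in vergence traces, and evaluation metrics
    (precision RMS and SD, accuracy, saccade and microsaccade metrics with a
    velocity-threshold event detector).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
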