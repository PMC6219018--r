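Package: somnopose
Title: Sleeping Posture Recognition from Pressure and Infrared Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes six sleeping postures from a 16x10 force-sensing
    resistor (FSR) bedsheet array imaging the upper body and an 8x8
    infrared thermal array (Grid-EYE) imaging the lower body. Implements
    moving-average denoising and threshold binarization, histogram
    projection with fuzzy c-means clustering to locate the trunk middle
    point and leg middle axis independently of where the subject lies,
    symmetry feature extraction, and a two-stage decision tree with
    distance-weighted k-nearest-neighbour classification. Includes a
    synthetic frame simulator for labelled pressure/thermal recordings,
    sensor-deployment geometry analytics (spatial sensing resolution,
    sensing gap, signal detection threshold), an evaluation report with
    per-weight-class accuracies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
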