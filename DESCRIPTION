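Package: rmpee
Title: Energy Expenditure Estimation from Respiratory Magnetometer
    Plethysmography with Temporal Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates per-window energy expenditure (kcal/min) and oxygen
    uptake from four-channel respiratory magnetometer plethysmography (RMP)
    distance signals sampled at 15 Hz, using a temporal convolutional
    network (TCN) regressor trained against breath-by-breath indirect
    calorimetry. Includes a graded-exercise respiratory simulator (subject
    profiles, sitting/standing + rest + ramp protocols, gas exchange with
    two ventilatory-threshold breakpoints, and a multi-compartment
    chest-wall forward model for the distance traces), sliding-window
    segmentation with breath-aligned targets, respiratory-equivalents
    ventilatory-threshold detection, the TCN with dilated causal
    convolutions and residual blocks trained by Adam on mean squared error,
    and an evaluation suite (R-squared, RMSE, Bland-Altman limits of
    agreement, per-intensity paired comparisons, window sample-size
    bookkeeping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
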