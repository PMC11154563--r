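Package: ppghb
Title: Non-Invasive Hemoglobin Estimation from Multiwavelength Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for estimating total hemoglobin concentration from
    multiwavelength transmissive photoplethysmography (PPG). Provides a
    Beer-Lambert forward simulator for eight-channel finger PPG (seven
    narrowband LEDs plus one broadband LED) with known ground truth, a
    filtering and landmark-detection chain, sliding-window-variance
    extraction of the pulsatile (AC) and static (DC) intensity components
    and their per-wavelength ratios, a cost-sensitive boosting (AdaCost)
    signal-quality classifier, and a regression suite (boosted trees,
    two-hidden-layer neural network, random forest) with grid search,
    cross-validation, and Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    rpart,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
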