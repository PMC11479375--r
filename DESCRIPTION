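Package: mear
Title: Spatiotemporal Gait Segmentation from an Ear-Worn Accelerometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects initial and final foot contacts from 100 Hz triaxial
    ear-worn accelerometer recordings with a temporal convolutional network,
    regresses stride length and stride width per gait cycle with causal
    residual TCNs, and derives bout-level gait analytics (mean, stride-to-stride
    variability, left-right asymmetry of stride time, swing time, double
    support time, stride length and stride width). Includes a synthetic gait
    cohort simulator emulating walkway protocols at slow, preferred and fast
    speeds, a group-aware training harness with cross-validated grid search,
    and method-agreement statistics (event matching at a time tolerance,
    precision/recall/F1, RMSE, Pearson correlation, intraclass correlation,
    repeated-measures ANOVA across speeds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
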