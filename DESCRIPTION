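Package: croptrack
Title: Tracking-via-Segmentation Crop Monitoring from RGB-D Row Traverses
Version: 0.1.0
Authors@R: person("Row", "Monitor", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Platform-agnostic crop and fruit monitoring from robot row
    traverses. Given per-frame instance segmentation masks with super- and
    sub-class labels, registered depth, camera calibration and wheel
    odometry, the package tracks each plant or fruit across a row using
    greedy tracking-via-segmentation (intersection-over-union or
    dynamic-radius matching, optionally with odometry-based mask
    reprojection), filters detections by metric depth windows, estimates
    per-object surface area from depth, and reports per-row yield counts
    and area statistics. Includes the full evaluation-metric suite
    (precision/recall/F1, instance and semantic segmentation IoU, confusion
    accuracy, mean normalized absolute count error, R squared) and a
    synthetic RGB-D scene simulator with detector-corruption models for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
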