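Package: stereodcm
Title: Per-Pixel Correction of Fine Pincushion Distortion in Close-Up Stereo Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and applies a per-pixel Distortion Correction Matrix
    (DCM) for the fine, left/right-asymmetric pincushion distortion seen in
    close-up mobile-phone stereo images of the skin surface. Includes
    generators for vertical-line calibration patterns and depth-stepped
    scalar bars, a pinhole stereo simulator with division-model ground-truth
    distortion, subpixel line detection and corresponding-line matching,
    forward-mapping image correction with nearest-neighbour hole filling,
    and the linear regression relating working distance to the maximum
    distortion ratio. All validation runs on synthetic stereo pairs with
    known ideal geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
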