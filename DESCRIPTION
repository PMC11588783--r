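Package: usborder
Title: Distinct and Completed Border Analysis for Ultrasound Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinician-inspired evaluation toolkit for ultrasound
    segmentation. Anatomical borders in expert annotations are split into
    distinct segments (supported by visible edge evidence, detected as a
    thresholded smoothed Sobel gradient of the image) and completed segments
    (interpolated by the annotator where the image carries no edge signal).
    Standard boundary metrics (Dice, 95th-percentile Hausdorff distance,
    normalized surface distance) and a true-positive decomposition of
    predicted borders are computed separately on each part, and Seg-Grad-CAM
    localization maps explain what a segmentation model attends to when
    scoring each border type. Ships an ultrasound-like speckle phantom
    generator with known border structure and small trainable model fixtures
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
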