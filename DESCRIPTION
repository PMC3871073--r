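Package: veinroi
Title: Robust ROI Localization for Near-Infrared Finger-Vein Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes the region of interest (ROI) in near-infrared finger-vein
    images through directional edge-operator segmentation, variance-gated
    repair of broken finger contours (boundary padding, re-binarization,
    single-linkage pruning of erroneous midline points, and line-guided
    false-background removal), least-squares orientation correction, and
    knuckle reference-line detection by block vertical projection. Includes a
    seedable synthetic NIR finger-image generator with analytic ground truth
    (mask, tilt angle, knuckle column) for validating every pipeline branch,
    plus an evaluation harness for segmentation accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    EBImage,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
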