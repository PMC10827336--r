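Package: lascaTrack
Title: Laser Speckle Contrast Imaging with Automatic ROI Tracking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Laser speckle contrast analysis (LASCA) of raw speckle image
    sequences: spatial and temporal speckle-contrast maps, relative
    flow-index (1/K^2) images, threshold-based background segmentation, and
    colour-coded perfusion rendering. Regions of interest (circles or
    polygons) are tracked across frames with a discriminative correlation
    filter using spatial and channel reliability, and repositioned under a
    displacement-threshold rule so that perfusion time series follow a
    moving lesion. Agreement between reference and automatically tracked
    traces is quantified with the two-way random intraclass correlation
    coefficient. A dynamic-speckle simulator with fully developed speckle
    statistics, per-region decorrelation times, occluding lesion patches and
    rigid motion provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
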