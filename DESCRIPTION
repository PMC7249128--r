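Package: stemyield
Title: Stem Detection and Yield Mapping from Depth-Camera Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects willow tree stems in aligned grayscale and depth frame
    pairs captured by a tilted stereo depth camera riding along a
    short-rotation forestry row, estimates each stem's diameter in
    millimetres from its bottom-row pixel width and depth, and geotags
    per-frame counts and diameters into a yield transect using raw NMEA
    GPS logs. The segmentation combines a tilted depth-threshold plane,
    contrast-limited adaptive histogram equalization, dynamic histogram
    thresholding and seed-point fixed-range flood fill; detection filters
    contours by area and bottom-row presence. A synthetic scene generator
    renders frame pairs with exact ground truth so every stage is testable
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
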