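Package: lanecam
Title: Automated Top-View Depth-Image Acquisition and Morphometrics for
    Walk-Through Livestock Lanes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating automated top-view depth-image
    acquisition systems over walk-through livestock lanes. Provides a
    synthetic depth-scene simulator (pinhole camera over a lane, half-ellipsoid
    animal bodies, sensor dropout and jitter), point-of-interest triggered
    picture- and video-capture state machines, a contour-based depth-image
    segmentation chain with morphological closing, top-view body morphometrics
    (height, width, length), six-category image grading, and success-rate and
    storage accounting. A 16-bit PNG frame store with a JSON manifest serves
    as the interchange format, so every stage is testable without camera
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: zlib
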