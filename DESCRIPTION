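Package: facemetrics
Title: Photograph-Based Facial Anthropometry with Corneal Diameter Calibration
Version: 0.1.0
Authors@R:
    person("Face", "Metrics Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic two-dimensional facial anthropometry from named
    landmark sets. Converts pixel distances to absolute millimetre distances
    by segmenting the corneal white-to-white (WTW) boundary with a
    region-based active contour, fitting a circle to the limbus, and scaling
    by a population reference WTW diameter. Computes a battery of roughly 25
    clinical facial measurements (facial thirds, canthal tilt corrected for
    in-plane head rotation, brow geometry, widths, and aesthetic ratios),
    cohort-level sexual-dimorphism statistics, and ships a synthetic-face
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
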