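Package: saberlever
Title: Planar Jaw Kinematics and Lever Mechanics for Sabertooth Bite Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Rigid-body kinematics and lever mechanics for testing
    craniomandibular bite hypotheses on a 2D landmark model of a
    sabertooth cat skull, neck and mandible.  Provides a seeded synthetic
    landmark generator for the neck-cranium-mandible chain, pivot
    rotation experiments with alternative mandible policies (including
    the stationary-mandible feasibility test of neck-powered biting),
    jaw lever classification and mechanical advantage, and a strike
    model in which the cranium rotates about the virtual center of the
    maxillary canine curvature.  Landmark I/O in named JSON, CSV and TPS
    formats, SVG scene export and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
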