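Package: antwatch
Title: Automated Image-Based Monitoring of Red Wood Ant Mound Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies red wood ant (Formica rufa group) activity on a
    mound top from fixed dual-sensor (daytime color / night-time
    near-infrared) camera frames. Implements translation registration by
    normalized cross-correlation over interest points, a masked,
    noise-thresholded frame-difference activity index, calibration of the
    raw index onto an eight-level manual activity scale by per-sensor-mode
    polynomial regression with temporal median filtering, earthquake
    catalog filtering and event-locked window extraction with a nocturnal
    rest-suppression flag, and a Hough-transform analysis of preferential
    mound alignment directions. A synthetic scene generator provides
    ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
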