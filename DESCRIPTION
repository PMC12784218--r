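Package: sarcbundle
Title: Regional Sarcomere Detection and Contractility Analysis for 2D
    Cardiac Muscle Bundles
Version: 0.1.0
Authors@R:
    person("sarcbundle", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frame-by-frame analysis of high-frame-rate fluorescence movies
    of beating two-dimensional cardiac muscle bundles (2DMBs). Detects
    z-discs and sarcomeres in every frame, segments the tissue with a
    classical computer-vision pipeline (noise suppression, Gaussian blur,
    Otsu threshold, convex hull, minimum-area rotated rectangle),
    partitions sarcomeres into longitudinal thirds and transverse halves,
    denoises regional average-sarcomere-length signals with Gaussian
    process regression using a Periodic + RBF + Matern (nu = 2.5) sum
    kernel, detects contractile phases with a Savitzky-Golay derivative
    heuristic, and extracts a comprehensive table of structural and
    functional metrics with paired drug-effect comparison. Includes a
    synthetic movie generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
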