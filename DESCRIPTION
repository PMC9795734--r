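Package: vabtrack
Title: Quantification of Vibration Attraction Behavior from Markerless Pose Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and behavioral quantification of markerless
    pose-estimator tracks from the vibration attraction behavior (VAB) assay
    in Astyanax mexicanus: confidence-threshold quality control with linear
    interpolation of low-likelihood frames, detection of left- and
    right-sided approaches toward a vibrating rod (NOA), adherence durations
    inside and outside a radius cutoff (DIR/DOR), swim distance, radius-scan
    selection of the cutoff, and downstream laterality statistics
    (left-right ratios and bias indices, preference categories, intraclass
    correlation repeatability, Kendall rank correlations, paired Wilcoxon
    tests with Holm correction). Includes a synthetic-trajectory generator
    with known ground truth so the whole pipeline is testable without video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
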