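Package: contoureval
Title: Multi-Observer Evaluation of Tumour Contouring Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-observer tumour contouring studies in
    radiotherapy: STAPLE expectation-maximisation consensus segmentation with
    per-rater sensitivity/specificity estimation, Dice similarity coefficient
    and added path length (APL) agreement metrics with a distance tolerance,
    signed surface-deviation percentile maps projected onto the consensus
    shape, and segmentation of interaction-event logs into active, observation
    and excluded contouring time. A synthetic observer-study generator
    (star-convex tumour-like shapes, annotator panels with separable inter-
    and intra-observer variability, voxel-flip raters with known performance,
    and renewal-process session logs) lets the full analysis run end to end
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
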