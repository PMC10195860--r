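Package: GazeBias
Title: Spatiotemporal Gaze Bias Toward Hierarchical Visual Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how strongly, and how early, the human gaze is
    attracted to visual features of different hierarchical complexity during
    free viewing of natural scenes. From fixation event tables and
    per-stimulus feature maps (gradient back-projections of convolutional
    network layers, or a from-scratch Itti-Koch saliency model) the package
    computes the gaze-attraction relative occupancy statistic, its
    millisecond time course, spatial and temporal gaze-bias indices with
    randomization-based chance levels, fixation-order and latency summaries,
    and the associated repeated-measures inference. A synthetic-data module
    generates feature fields and scanpaths with known ground-truth bias for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
biocViews: EyeTracking, Visualization, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
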