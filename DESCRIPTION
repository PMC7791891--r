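Package: immunoseg
Title: Evaluation and Simulation of Immune-Cell Instance Segmentation in
    Multiplexed Fluorescence Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying multi-class immune-cell instance
    segmentation of multiplexed immunofluorescence tissue images. Provides a
    synthetic tissue simulator that generates ground-truth cell cohorts and
    degrades them into realistic predictions (missed cells, false positives,
    boundary jitter, misclassification, confidence scores); cell-level
    evaluation by one-to-one IOU-threshold matching with per-class
    sensitivity, specificity and IOU; cell morphometry (area, perimeter,
    equivalent diameter) and nearest-neighbour intercellular distances in
    micrometres; and cohort comparison statistics (two-sample
    Kolmogorov-Smirnov tests, percent change of means, population tables,
    reproducible train/validation/test splits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
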