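Package: speckleQuant
Title: Quantitative Analysis of Nuclear Speckle Dynamics from Fluorescence
    Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify punctate sub-nuclear structures (nuclear
    speckles) in time-lapse fluorescence microscopy. Provides speckle
    segmentation and morphometry (rolling-ball background subtraction, Li
    threshold, watershed splitting, size filtering), single-particle
    detection and frame-to-frame linking, per-trajectory speed and
    moment-scaling-spectrum (SMSS) motion classification, FRAP and FLIP
    photobleaching trace normalization and single-exponential fitting
    (mobile fraction, half-time), and Costes automatic thresholding with
    thresholded Manders co-localization coefficients. A synthetic-data
    module generates ground-truth movies, trajectories, photobleach traces
    and two-channel image pairs so every stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    igraph,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Software
RoxygenNote: 7.3.3
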