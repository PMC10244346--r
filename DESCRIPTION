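Package: pscdiff
Title: Image-Based Machine Learning Control of Pluripotent Stem Cell
    Differentiation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free monitoring and control of pluripotent stem cell
    (PSC) differentiation from whole-well bright-field microscopy.
    Implements differentiation-efficiency quantification from
    fluorescence labels, early CHIR-dose assessment from 0-12 h
    bright-field image streams (fractal dimension, local-entropy colony
    statistics, dense optical flow), morphological profiling of initial
    PSC colonies with random-forest efficiency prediction, weakly
    supervised progenitor/endoderm region localization via
    gradient-weighted class-activation maps, compound-screen ranking,
    and a scaled-down conditional-adversarial bright-field-to-
    fluorescence translator, together with a synthetic well generator
    that makes every component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    png,
    glmnet,
    ranger,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Software, Classification, Regression,
    FeatureExtraction
RoxygenNote: 7.3.3
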