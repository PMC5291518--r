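Package: microbleedR
Title: Quantification of Cerebral Microbleeds in Stained Brain Sections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated, unbiased quantification of cerebral microbleeds in
    RGB images of stained coronal brain sections. Detects extravasated-blood
    pixels with a hard-margin linear support vector machine trained on
    hand-labeled pixels in the (green, blue) channel plane, extracts
    individual microbleeds as 8-connected components with calibrated areas,
    circular-equivalent diameters, per-plane totals, size-frequency
    histograms and hemisphere-folded spatial maps, quantifies specific
    immunolabeling as the percent of a region of interest exceeding twice
    background intensity, and reports group statistics (mean +/- SE, one-way
    ANOVA with Tukey post-hoc comparisons, fold changes). A synthetic
    histology generator with full ground truth makes every stage testable
    without the original tissue images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp,
    e1071,
    png,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Classification
RoxygenNote: 7.3.3
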