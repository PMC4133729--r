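Package: osteoquant
Title: Automated Quantification and Regulator Ranking for Human
    Osteoclastogenesis Imaging Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying human osteoclastogenesis from
    multi-channel fluorescence plate images and for ranking secreted
    cytokines as candidate regulators of osteoclast formation. Nuclei
    and alpha-v-beta-3-positive osteoclast cytoplasm are segmented by
    thresholding and connected-component labelling; each nucleus is
    classified as osteoclastic (inside a marker-positive region holding
    at least two nuclei) or monocytic; per-nucleus mean nuclear NFATc1
    intensity is gated into negative and positive populations at the
    minimum between the two modes of a fitted two-component Gaussian
    mixture; and a conditions-by-(cytokine, timepoint) predictor matrix
    is related to osteoclastogenesis outcomes by partial least squares
    regression (NIPALS and SIMPLS), with variable-importance (VIP) and
    coefficient scores summed over timepoints into cumulative regulator
    rankings. Ground-truthed synthetic image and cytokine-panel
    generators allow every stage to be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    mixOmics,
    optparse
Config/testthat/edition: 3
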