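Package: poriaNIR
Title: FT-NIR 2D Correlation Spectroscopy and Residual CNN Classification
    of Wolfiporia cocos with Habitat-Suitability Post-Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for authenticating wild versus cultivated Wolfiporia
    cocos (Poria and Poriae Cutis) from Fourier-transform near-infrared
    spectra. Provides a synthetic FT-NIR spectrum simulator with the band
    structure of W. cocos, generalized synchronous two-dimensional
    correlation spectroscopy (2DCOS) with contour-image export,
    Kennard-Stone sample-set partitioning, PCA score visualization, a
    12-layer residual convolutional neural network trained from scratch
    on 2DCOS images, and post-processing of species-distribution-model
    suitability rasters (Spearman collinearity filtering, main-factor
    selection, 0.5 thresholding, climate x soil x vegetation overlay and
    per-region area statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    png,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
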