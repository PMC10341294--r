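Package: gasegr
Title: Multimodal Deep-Learning Segmentation and Agreement Analysis of
    Geographic Atrophy on FAF/NIR Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for segmenting geographic atrophy (GA) lesions on paired
    fundus autofluorescence (FAF) and near-infrared reflectance (NIR) images
    with encoder-decoder convolutional networks (a single-encoder UNet on
    channel-stacked FAF+NIR and a dual-encoder YNet with FAF-only skip
    residuals), trained with an edge-reweighted soft Dice loss.  Includes
    lesion-mask utilities (minimum-area spot filtering, focality, lesion
    area in mm2), a cross-sectional and longitudinal agreement pipeline
    (Dice tables, Pearson correlation, Passing-Bablok regression,
    generalized multi-rater Bland-Altman limits, enlargement and coefficient
    of variation), and a synthetic fundus phantom generator producing
    registered FAF/NIR pairs with ground-truth masks, simulated grader
    annotations and longitudinal lesion growth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
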