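Package: dermoknn
Title: Dermoscopic Skin-Lesion Segmentation, ABCD-Style Features and
    K-Nearest-Neighbor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for benign-versus-melanoma classification of
    dermoscopic skin-lesion images: morphological hair removal and histogram
    equalization, adaptive-threshold segmentation, a frozen descriptor set of
    statistical, shape (asymmetry, compactness, Feret diameter) and color
    features, and a K-nearest-neighbor classifier with accuracy-plot K
    selection. Includes a fully parameterized synthetic lesion-image generator
    with ground-truth masks so every stage is testable without an external
    dermoscopy dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
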