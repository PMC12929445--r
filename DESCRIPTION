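Package: safpn
Title: Split-Attention Feature Pyramid Networks for Crop Classification
    from Satellite Image Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-pixel crop classification from multi-temporal multispectral
    satellite imagery with a hybrid (3+2)D split-attention feature pyramid
    network. Provides raster time-series input/output and patch gridding,
    leakage-free patch-level dataset splitting, NDVI computation, a synthetic
    scene generator with double-logistic crop phenologies and parcel-structured
    labels, the split-attention network itself (3D spatiotemporal stem, 2D
    feature pyramid with radix-softmax channel attention, classification and
    NDVI regression heads) with hand-written forward and backward passes,
    a focal + NDVI-regression training objective, SGD training with early
    stopping, confusion-matrix accuracy assessment (overall accuracy,
    precision, recall, F1, Cohen's kappa), temporal class-activation profiles,
    full-scene map inference, and pixel-count to planted-area statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
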