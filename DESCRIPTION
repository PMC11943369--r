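Package: weedseg
Title: Plant and Weed Segmentation in Broadband Multispectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage semantic segmentation of crops and weeds in co-registered
    eight-band visible (VIS) and near-infrared (NIR) multispectral images. A
    dual-branch convolutional fusion network (PIF-Net) with channel attention
    merges VIS and NIR features into a fused eight-band image that feeds a
    zero-padded U-Net classifier; a PCA three-band baseline and a
    normalized-NIR baseline are provided for comparison. Includes simulation of
    snapshot multispectral filter array (MSFA) capture and demosaicking, a
    chroma-based ground-truth annotation pipeline (CIELAB conversion, K-means
    on the a/b chroma plane, connected-component instance extraction), a
    synthetic scene generator emulating soil/plant/weed imagery, and a full
    segmentation metric suite (Dice, IoU, boundary F1, precision/recall, RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tiff,
    png,
    yaml,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
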