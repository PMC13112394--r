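Package: strawbruise
Title: Dual-Band Hyperspectral Detection and Quantification of Strawberry Bruises
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and quantifying impact
    bruises on strawberries from Vis-NIR (380-1010 nm) and SWIR
    (1000-2000 nm) hyperspectral line-scan images. Provides ENVI cube
    input/output with white/dark reflectance calibration, fruit
    segmentation by Otsu thresholding with morphological refinement,
    achene removal by black-hat transform and leaf removal by NDVI
    thresholding, chemometric spectral preprocessing (band trimming,
    5-point moving average, first derivative) with Kennard-Stone
    calibration/validation splitting, a compact one-dimensional
    convolutional classifier built from mobile inverted bottleneck
    (MBConv) blocks with squeeze-and-excitation attention and compound
    scaling, reference PLS-DA/SVM/1D-CNN/LSTM baselines, and pixel-level
    bruised-area mapping with MAE/RMSE evaluation. A synthetic phantom
    generator produces hyperspectral strawberry scenes with known ground
    truth so the whole pipeline is testable without camera data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
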