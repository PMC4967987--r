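Package: fuzzyCT
Title: Fuzzy Clustering Segmentation of Thoracic CT for Nodule ROI
    Detection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Candidate-nodule region-of-interest detection in thoracic CT
    slices and volumes by fuzzy clustering of voxel attenuation values.
    Implements fuzzy c-means (FCM) together with its kernelized (KFCM),
    spatially regularized (SFCM), spatially penalized kernel (SKFCM), and
    combined kernel-plus-spatial (MSKFCM) variants, each usable with 2D
    in-slice or 3D rectangular-prism voxel neighborhoods.  Includes a
    synthetic CT phantom generator with ground-truth nodule masks,
    per-slice true-positive/false-positive scoring against binary or
    radiologist-consensus masks, Bowyer-style parameter sweeps tracing
    TP-vs-FP tradeoffs, readers and writers for NIfTI, TIFF and PNG
    volumes and LIDC-dialect XML nodule annotations, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    RNifti,
    png,
    tiff,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
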