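Package: capiflow
Title: Stabilization, Temporal Enhancement and Capillary Segmentation for
    Videocapillaroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for grayscale videocapillaroscopy of the
    oral mucosa. Provides feature-based rigid video stabilization (iterative
    Hessian-blob keypoint detection, descriptor matching with a cascaded
    good-match filter and displacement outlier rejection, closed-form rigid
    motion estimation), temporal signal enhancement based on sliding-window
    standard-deviation images, tile-based capillary segmentation with a
    small encoder-decoder convolutional network trained under
    leave-one-out cross-validation, segmentation quality metrics (Jaccard
    index, sensitivity, specificity, accuracy), and a synthetic capillary
    video phantom generator with ground-truth vessel masks and motion logs
    for dataset-free validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
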