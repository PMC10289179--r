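Package: neuroseg
Title: Weakly Supervised 3D Neuron Segmentation for Optical Microscopy Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments neuronal structures (neurites and somata) from 3D
    optical-microscopy image stacks without manual labels. An adaptive
    Hessian eigenvalue enhancement filter, with its analysis window driven
    by the Euclidean distance transform, generates pseudo-labels; a compact
    volumetric encoder-decoder network is trained on them with a mixed
    Dice / weighted-cross-entropy loss; seeded region growing on the
    predicted probability map mines weak neurites; probability/intensity
    fusion produces an enhanced input; and the loop iterates under a
    double-delta F1 convergence rule. Includes a synthetic phantom
    generator for fMOST-like volumes, multi-page TIFF I/O, test-time
    augmentation, and voxel-wise evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
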