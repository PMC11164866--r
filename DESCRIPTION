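Package: epuf
Title: Simulation and Authentication of Electrosprayed Edible Physical
    Unclonable Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for image-based authentication of drug tablets carrying
    edible physical unclonable functions (ePUFs): stochastic dye-spot
    patterns deposited by electrospray. Provides a seeded simulator of
    electrospray spot patterns and cellphone-like capture perturbations, the
    pattern-extraction chain (Otsu segmentation on HSV channels, rotated
    min-area crop), SIFT keypoint and descriptor extraction, descriptor
    matching with Lowe's ratio test and symmetry cross-checking, the
    prominence-threshold decision rule, reference-database management, and
    evaluation utilities (distance-ratio sweeps, leave-one-out
    cross-validation, specificity traces, precision-recall accuracy grids).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
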