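Package: canalseg
Title: Automated External Ear Canal Segmentation and Implant Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the external ear canal (EEC) from CT-like volumes using
    a truncated cylindrical volume of interest anchored on four anatomical
    control points, Gaussian smoothing, thresholding, and connected-component
    selection by proximity to the canal axis. Computes canonical geometric
    measurements (volume, length, width, height), builds hollow base-trimmed
    implant label maps and 3D-printable STL meshes via an anisotropic
    Euclidean distance transform, and provides validation metrics (Dice
    similarity, 95th-percentile Hausdorff distance, rigid ICP alignment, RMS
    surface distance). A synthetic temporal-bone phantom generator with
    analytically known canal geometry supports end-to-end testing without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
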