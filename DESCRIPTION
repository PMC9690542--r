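Package: spinemorph
Title: Spine MRI Segmentation and Normative Morphometry with an
    Anisotropic Residual 3D U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of sagittal T2-weighted spine MRI:
    voxel-wise semantic segmentation of vertebral bodies, intervertebral
    discs and the spinal canal with a depth-IV residual 3D U-Net whose
    kernels respect the anisotropy of thick-slice sagittal acquisitions;
    patch-based training with focal cross-entropy and in-plane
    augmentation; tiled whole-volume inference with voxel-wise precision,
    recall and Dice evaluation; morphometry of the segmented structures
    (disc volumetry, PCA disc-plane fitting, convex-hull paraxial canal
    area); and age-, sex- and height-stratified normative reference
    tables.  A parametric spine-phantom generator with analytically known
    morphometry makes every stage testable without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    optparse,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
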