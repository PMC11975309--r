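Package: gaussCBCT
Title: Time-Resolved Dynamic Cone-Beam CT Reconstruction with 3D Gaussian Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a time-resolved dynamic cone-beam CT sequence (one volume
    per x-ray projection) from a single conventional CBCT scan, without prior
    anatomical or motion models. The anatomy is represented by a dense set of 3D
    Gaussian kernels forming a reference-frame volume; intra-scan respiratory motion
    is modelled by three coarse-to-fine levels of signed Gaussian motion-basis
    components whose per-projection coefficients are produced by a small
    convolutional encoder. Includes a differentiable splatting-based x-ray
    rasterizer, Gaussian voxelizers (positive and negative-permitting), a Joseph
    cone-beam forward projector with exact adjoint, FDK reconstruction for
    initialization, a programmatic 4D thorax phantom with analytic ground-truth
    motion for end-to-end testing, and evaluation metrics (relative error,
    volumetric SSIM, tumor center-of-mass error, Dice, Amsterdam-Shroud motion
    traces).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
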