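Package: petray
Title: Joseph Ray-Driven TOF PET Projectors with Matched Adjoints and
    OSEM Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ray-driven tomographic projection and reconstruction for
    positron emission tomography (PET). Implements Joseph's method
    (plane-by-plane stepping with bilinear interpolation) for 3D volumes
    with anisotropic voxels, its time-of-flight (TOF) extensions in both
    sinogram and listmode form, and back projectors that are the exact
    adjoints of the forward projectors. Includes a cylindrical multi-ring
    scanner geometry model with interleaved sinogram indexing, MLEM/OSEM
    reconstruction (sinogram and listmode) with an image-based Gaussian
    resolution model, a synthetic NEMA-like phantom and Poisson/multinomial
    listmode event simulator, sinogram memory-layout utilities and a
    projector benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
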