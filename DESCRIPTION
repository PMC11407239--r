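Package: fdot
Title: Hybrid Model-Based and Learned Fluorescence Diffuse Optical Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-step fluorescence diffuse optical tomography (fDOT) for
    cylindrical vessels such as bench-top bioreactors. A continuous-wave
    diffusion forward model with Robin boundary conditions is solved by a
    voxel finite-volume scheme, normalized Born ratios are inverted by
    Tikhonov regularization, and the resulting volume is enhanced by a 3D
    residual encoder-decoder network trained on simulated phantom cases.
    Also provides time-resolved optical-property estimation from temporal
    point spread functions via instrument-response conditioning and a
    weighted grid search, camera-image preprocessing (cylindrical unwrapping,
    saturated-spot removal, median smoothing, neighborhood sampling), and
    volumetric evaluation metrics (thresholded IoU, center-of-mass bias,
    FWHM, subregion SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
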