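Package: prfrecon
Title: Visual Field Reconstruction and Imagery Decoding from Population
    Receptive Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates retinotopically organised voxel populations with
    Gaussian population receptive fields (pRFs), fits pRF position and size
    parameters by grid search on bar-aperture mapping runs, and inverts the
    resulting voxel-by-pixel encoding matrix with outdegree-scaled Tikhonov
    regularisation to reconstruct letter shapes from voxel activation
    patterns.  Includes a tied-weight denoising autoencoder that projects
    noisy mental-imagery patterns onto perceptual attractors, a frozen-encoder
    softmax classifier with leave-one-run-out cross-validation, and
    permutation-based significance testing of decoding accuracy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
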