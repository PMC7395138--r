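Package: exmetry
Title: Validation Analytics for Expansion Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative validation toolkit for expansion microscopy (ExM)
    experiments: linear expansion-factor estimation from nuclear
    cross-sectional areas and landmark crops, registration-based distortion
    metrology (similarity/affine pre-registration followed by B-spline
    free-form non-rigid registration, summarised as RMS error versus
    measurement length), organelle morphometry from thick line profiles
    (cristae and Golgi spacings, tubule diameters, centriole roundness and
    length-to-width ratios), and background-corrected fluorescence retention
    quantification. A ground-truthed synthetic phantom generator simulates
    pre- and post-expansion image pairs (Gaussian PSF, Poisson-Gaussian
    noise, global scale x shear x smooth non-rigid deformation) so every
    estimator can be checked against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
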