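Package: ellipstack
Title: Stacked-Ellipse Statistical Shape Models for Semiautomatic Organ
    Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a smooth organ (primarily the prostate in axial MR) as a
    stack of slice-wise best-fitting ellipses. Provides orthogonal-distance
    ellipse fitting, inter-slice parameter correspondence (axis reordering,
    circularity relaxation, rotation smoothing, cubic resampling), control-point
    driven registration into a common sample space, per-slice Gaussian and
    log-normal shape priors trained from a population, deformation of the mean
    shape into a new case from 18 boundary control points, optional Markov chain
    Monte Carlo refinement against image gray levels, Dice/Hausdorff/accuracy
    evaluation, a synthetic phantom generator for end-to-end validation, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    mgcv,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
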