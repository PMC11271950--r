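Package: fatnavsim
Title: Simulation of Head-Motion Effects on GRAPPA-Reconstructed 3D Fat-Navigator MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Synthetic-data pipeline for studying how large head motion degrades
    highly accelerated 3D fat-navigator (FatNav) volumes reconstructed with GRAPPA,
    how that degradation biases navigator-derived rigid-motion estimates, and how the
    resulting residual motion maps onto image-quality categories of a motion-corrupted
    3D T1-weighted brain volume. Provides an analytic head phantom with a subcutaneous
    fat shell, smooth complex coil-sensitivity simulation and estimation, Cartesian
    undersampling and GRAPPA calibration/reconstruction, 6-DOF rigid transforms and
    sum-of-squared-differences registration, fractal-noise motion-trace generation,
    shot-wise k-space motion corruption, gradient-entropy image quality scoring,
    simulated ordinal observers, and the statistical layer (Krippendorff's alpha,
    multinomial logistic regression, RMS and framewise-displacement regression models
    inverted to motion-tolerance boundaries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    nnet,
    minpack.lm,
    RNifti,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
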