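Package: ogdenqlv
Title: Ogden Hyperelastic and Quasi-Linear Viscoelastic Soft-Tissue Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward modelling and calibration of soft biological tissue
    under simple shear and uniaxial tension. Implements the incompressible
    Ogden hyperelastic stress response in principal stretches, a
    Prony-series quasi-linear viscoelastic (QLV) hereditary convolution
    with a fast recursive exponential integrator and an independent
    trapezoidal quadrature oracle, simultaneous multi-strain-rate
    nonlinear least-squares parameter estimation from replicate
    stress-strain curves, a synthetic replicate-data generator that
    emulates mean/SEM experimental reporting, and text-based curve,
    material-card and parameter-table input/output with a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
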