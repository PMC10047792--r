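Package: eitshape
Title: Implicit Shape Reconstruction for Electrical Impedance Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inversion toolkit for the two-dimensional
    electrical impedance tomography (EIT) shape-reconstruction problem on the
    unit disk. Provides a P1 finite-element forward solver under the
    point-electrode adjacent-pair protocol (16 electrodes, 208 voltage
    differences), random circular-anomaly phantom and dataset generation, an
    implicit coordinate-based classifier (measurement encoder, point encoder
    and decoder built from fully connected residual blocks) trained with ADAM
    to label arbitrary points of the domain as background or anomaly, a
    monotonicity-test baseline using precomputed Neumann-to-Dirichlet
    operators of small balls, and iteratively regularized Gauss-Newton
    conductivity reconstruction in standard, shape-constrained and
    piecewise-constant variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    deldir,
    jsonlite,
    methods,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    tidyr
Config/testthat/edition: 3
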