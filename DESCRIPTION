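Package: azir
Title: Azimuthal Integration and Geometry Calibration for 2-D Diffraction Images
Version: 0.1.0
Authors@R: person("azir", "developers", email = "azir@example.org", role = c("aut", "cre"))
Description: Data reduction for powder-diffraction and small-angle scattering
    images recorded on flat area detectors. Implements the six-parameter PONI
    (point of normal incidence) detector geometry, ring-based geometry
    calibration from Debye-Scherrer rings (massif extraction, subpixel peak
    refinement, difference-of-Gaussians blob detection, bounded least-squares
    refinement), 1-D and 2-D azimuthal integration with three pixel-splitting
    schemes via direct histogramming or a precomputed CSR sparse rebinner,
    Poisson and azimuthal error models, isotropic/Bragg image separation, and
    a synthetic calibration-image generator used as the test fixture engine.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
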