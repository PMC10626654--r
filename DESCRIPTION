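Package: saxstt
Title: Small-Angle Scattering Tensor Tomography with Band-Limited
    Spherical Harmonics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs, in every voxel of a three-dimensional volume, a
    band-limited even-order spherical-harmonic representation of the
    reciprocal-space map from azimuthally binned scanning small-angle
    X-ray scattering (SAXS) projections acquired at multiple rotations and
    tilts. Provides an exact ray-traced John (X-ray) transform and its
    adjoint for multi-channel coefficient volumes, regularized
    least-squares reconstruction with a nearest-neighbour smoothness
    penalty, a rank-2-restricted mode, ensemble reconstructions with
    randomized initialization, rotation-invariant evaluation metrics
    (cross-spectrum, anisotropic power, relative anisotropy, squared
    Pearson correlation, ensemble power quotient), a synthetic-phantom
    simulator with three texture symmetry classes, and a simple dataset
    container with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    pracma,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
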