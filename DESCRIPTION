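Package: mwtomo
Title: Microwave Tomographic Imaging with a Discrete-Dipole Forward Solver
    and a Collapsed Nodal-Adjoint Jacobian
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional microwave tomographic image reconstruction for
    circular antenna arrays immersed in a lossy coupling bath. Provides a
    node-collocated volume-integral (discrete-dipole) forward solver for the
    2D TM scattering problem, exact sensitivity (Jacobian) matrices built by
    the nodal-adjoint method in its collapsed form (one vector-vector product
    of two forward field distributions per matrix row when the forward and
    parameter grids coincide), log-magnitude/phase Gauss-Newton image
    reconstruction with homogeneous-tank calibration, and a synthetic phantom
    simulator so the full pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
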