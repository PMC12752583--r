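Package: pinnelast
Title: Physics-Informed Neural Network Elastography for Plane-Stress
    Elasticity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers spatially heterogeneous Young's modulus and Poisson's
    ratio fields from noisy two-dimensional displacement measurements under
    the plane-stress linear elasticity model. Phase 1 jointly trains three
    sine-activated coordinate networks (displacement, strain, elasticity)
    against a four-term loss combining data fit, strain consistency,
    finite-difference equilibrium residuals, and a mean-modulus anchor,
    producing relative-scale elasticity maps. Phase 2 calibrates the
    absolute modulus scale from a known applied boundary force. A built-in
    bilinear-quadrilateral finite element forward solver, elasticity
    phantom generators, and Gaussian and ultrasound-style structured noise
    models make the inverse method testable end-to-end without external
    data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
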