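Package: skinwave
Title: Simulated Tissue Expansion and Elastic-Wave Inference of Skin Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A volumetric-growth hyperelastic simulator of skin under
    tissue expansion, together with the inverse machinery to recover skin
    properties from non-invasive surface-wave measurements. The package
    implements a compressible neo-Hookean material with multiplicative
    elastic/growth kinematics and a stretch-driven areal growth law, a
    small total-Lagrangian finite-element engine (static Newton solves for
    pre-stretch, expander inflation and growth relaxation; explicit
    central-difference dynamics for wave excitation), a Latin-hypercube
    virtual-cohort generator, the simulated clinical measurement protocol
    (baseline, day-0 and day-3.5 waveforms plus the day-7 growth field),
    and a multilayer-perceptron surrogate that maps the three waveforms to
    the subject's shear modulus, growth rate, natural pre-stretch and the
    coarsened 5x5 growth field, evaluated by repeated 10-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite,
    lhs,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
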