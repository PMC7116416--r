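Package: shellopt
Title: Data-Driven Optimisation of Multi-Shell Diffusion MRI Acquisition Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs multi-shell diffusion MRI acquisition protocols from
    pilot data. Extracts per-shell mean diffusion-weighted signals within a
    brain mask, derives a data-driven orthonormal signal basis over b-values
    by singular value decomposition, propagates measurement noise into
    coefficient contrast-to-noise ratios, allocates a fixed volume budget
    across shells by a closed-form Lagrange solution, and searches for
    optimal shell b-values by monotone interpolation and simplex
    minimisation of the sum of squared coefficients of variation, with an
    echo-time/T2 penalty for high b-values. Includes spherical-harmonic
    angular-content analysis to determine minimum per-shell direction
    counts, electrostatic-repulsion direction generation, and a synthetic
    multi-compartment phantom generator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
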