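Package: rtfde
Title: Real-Time TDDFT with Uncoupled Frozen-Density Embedding in Gaussian Basis Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates electron dynamics of a closed-shell active molecule
    embedded in a frozen molecular environment. Implements a self-contained
    Gaussian-basis Kohn-Sham LDA backend (McMurchie-Davidson integrals),
    molecular quadrature grids, frozen-density-embedding potentials built from
    nonadditive Thomas-Fermi kinetic and LDA exchange-correlation functionals,
    split-SCF polarized ground states, density-matrix propagation with the
    second-order midpoint Magnus propagator and a predictor/corrector scheme,
    delta-kick and cos2-envelope laser fields, Pade-accelerated dipole strength
    functions, high-harmonic-generation power spectra, and a Casida
    linear-response solver used for cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
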