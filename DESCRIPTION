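Package: smarphase
Title: Dual-Space Direct-Methods Phasing with the SMAR and Delta-Recycling
    Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves the crystallographic phase problem for equal-atom
    structures at atomic resolution by iterative dual-space recycling.
    Implements the SMAR phasing algorithm (alternating chi and Phi phasing
    formulas built on the absolute value of the electron density and the
    zero conversion of slightly negative Fourier ripples), the delta_M
    tangent-formula recycling algorithm, the inner-pixel-preservation (ipp)
    density modification, per-voxel density masks, and the full set of
    normalized residuals and diagnostics (S_delta, P, Q, R_delta, SRO2,
    SDEL, CC, k_deltaP, R_rho). A synthetic-data module generates random
    equal-atom P1 crystal structures with exact point-atom structure
    factors for validation; reflection, phase and map file I/O and a thin
    command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
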