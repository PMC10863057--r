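Package: atpsdiagram
Title: Phase-Diagram Inference for PEG-Dextran Aqueous Two-Phase Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing and exploiting the phase diagram of a
    PEG-dextran aqueous two-phase system (ATPS). Fits the binodal curve to
    cloud-point titration data by nonlinear least squares, solves tie-line
    endpoint compositions from gravimetric phase-separation experiments via
    mass balances, computes lever-rule phase fractions and density-corrected
    dextran:PEG volume ratios, interpolates tie-lines at unmeasured
    compositions through a quadratic conjugate curve, and propagates
    measurement and fit uncertainty by Monte Carlo resampling. Also includes
    phenomenological models linking ATPS formulation variables to microgel
    material properties (with PRESS-based predicted R-squared diagnostics),
    a polydispersity index for particle diameters, a Bartlett-gated
    parametric/nonparametric group-comparison router, and a synthetic
    experiment generator so the full pipeline can be exercised and validated
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
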