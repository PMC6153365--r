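Package: gmpfate
Title: Dynamical Modeling of Cytokine-Driven Granulocyte-Monocyte Progenitor Fate Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an eight-protein sigmoidal ordinary differential
    equation model of granulocyte-monocyte progenitor (GMP) differentiation
    driven by the colony stimulating factors M-CSF, G-CSF and GM-CSF. The
    network couples the master regulators PU.1 and C/EBP with Gfi-1, Egr-2,
    IRF8 and the three cognate cytokine receptors, including mass-action
    sequestration of C/EBP by IRF8. The package provides trajectory
    integration, pseudo-phase-plane nullcline computation, steady-state
    location with eigenvalue stability analysis, one-parameter bifurcation
    continuation with saddle-node handling, hysteresis scans, and stochastic
    population simulations with phenotype composition tables and RGB fate
    heat maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
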