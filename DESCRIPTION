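Package: sacflow
Title: Desk-Scale Fluid-Structure Interaction Analysis of Sidewall Aneurysm Haemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic sidewall-aneurysm geometry generation (bulge surfaces mounted on an
    idealized toroidal artery), a reduced two-dimensional strongly coupled fluid-structure
    solver (stabilized equal-order incompressible Navier-Stokes in an arbitrary
    Lagrangian-Eulerian frame, Neo-Hookean mixed displacement-pressure hyperelasticity,
    Aitken-accelerated Dirichlet-Neumann partitioned coupling), the standard haemodynamic
    risk-indicator battery (time-averaged wall shear stress, oscillatory shear index,
    kinetic-energy and viscous-dissipation ratios, shear-area and concentration indices),
    rigid-versus-compliant cohort statistics, and a parametric braided flow-diverter
    analog with porosity computation and two-dimensional mesh immersion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
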