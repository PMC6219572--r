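Package: wedgelat
Title: Bilayer-Mediated Interactions and Self-Assembly of Amphipathic
    Protein Wedges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuum elastic model of lipid bilayer thickness deformations
    induced by partially inserted amphipathic helices (protein "wedges"), such
    as the N-terminal H0 helices of N-BAR domain proteins.  Provides the exact
    analytic solution of the one-dimensional Euler-Lagrange boundary-value
    problem for one or two parallel wedges and the resulting bilayer-mediated
    interaction potential as a function of separation, immersion depth and
    membrane tension; a two-dimensional finite-difference solver for leaflet
    thickness deformations around stadium-shaped wedge footprints, yielding
    directional pair-potential tables; rigid-body Metropolis Monte Carlo with
    simulated annealing for N-BAR self-assembly under tabulated wedge
    potentials and a modified Lennard-Jones scaffold potential; and the pair
    statistical mechanics of the concerted shallow-to-deep conformational
    switch, including Mayer-f weighted Boltzmann weights and deep-state
    probability phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
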