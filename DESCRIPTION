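Package: cononsolv
Title: Coil-Globule Free Energies of a Generic Polymer in Binary Solvents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale free-energy pipeline for polymer cononsolvency: a
    32-bead Lennard-Jones polymer in a reduced water/alcohol solvent mixture,
    propagated by stochastic (Langevin) dynamics under periodic boundary
    conditions. Umbrella sampling along the radius of gyration with WHAM
    reconstruction yields the coil-globule collapse free energy; thermodynamic
    integration over soft-core Weeks-Chandler-Andersen polymer-solvent coupling
    isolates the solvent-excluded-volume (cavity) contribution for fixed coil
    and globule conformations; solvation analysis (solvent-accessible surface
    area, first-shell preferential adsorption, saturation concentration)
    quantifies the cosolvent surfactant mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
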