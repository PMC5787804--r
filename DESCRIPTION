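Package: dfspec
Title: Single-Molecule Dynamic Force Spectroscopy Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM)
    single-molecule force spectroscopy of receptor-ligand bonds pulled
    through a flexible polymer tether. Converts force-distance curves to
    unbinding events (rupture force, tether stiffness, effective spring
    constant, loading rate), estimates per-velocity binding probabilities
    and empirical rupture-force probability densities, extracts most
    probable unbinding forces by Gaussian fitting, and recovers Bell-Evans
    single-energy-barrier kinetic parameters (barrier width x_beta and
    zero-force dissociation rate k_off) from the dependence of force on the
    logarithm of the loading rate, with 95% confidence bands. Includes a
    physics-based generator of synthetic force-distance curve ensembles
    (Bell rupture kinetics, freely-jointed-chain tether, Gaussian
    instrument noise, nonspecific adhesion) so that every stage of the
    pipeline can be validated against ground truth, plus plain-text file
    formats and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
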