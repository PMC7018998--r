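Package: toccslr
Title: Two-Color TOCCSL Analysis of Membrane Receptor Dimerization
Version: 0.1.0
Authors@R:
    person("TOCCSL", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for two-color TOCCSL ("thinning out
    clusters while conserving stoichiometry of labeling") single-molecule
    experiments on membrane receptor dimerization, with ErbB2/ErbB3 as the
    motivating system. Provides a synthetic-data generator for Brownian
    monomer/dimer/heterodimer populations under a bleach/recovery protocol,
    single-molecule localization and two-channel bead registration, trajectory
    linking and MSD-based diffusion estimation, co-localization counting with
    mirror-based false-positive subtraction, corrections for labeling
    stoichiometry and diffusion-dependent recovery, a global competition model
    for monomer/homodimer/heterodimer composition, FRAP mobile-fraction
    fitting, and equilibrium binding-affinity fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
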