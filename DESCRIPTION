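Package: chiralvesicle
Title: Brownian Dynamics of Soft Vesicles Filled with Chiral Active Particles
Version: 0.1.0
Authors@R: person("Vesicle", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-dimensional overdamped Langevin (Brownian) dynamics of a soft
    vesicle, modelled as a flexible ring polymer with harmonic bonds and
    purely repulsive (WCA) excluded volume, enclosing chiral active Brownian
    particles that self-propel at speed V0 and self-rotate at angular
    velocity omega. Provides a compiled cell-list integrator, deterministic
    initial-configuration builders, trajectory I/O in extended XYZ, and the
    observables used to characterise such systems: cumulative vesicle
    rotation and its fitted angular velocity, membrane contact and
    tangential/normal force statistics, gyration-tensor asphericity,
    interior-angle fluctuations, local-curvature distributions,
    centre-of-mass mean-square displacement with multiple time origins, the
    closed-form chiral-swimmer MSD theory, and a one-parameter effective
    diffusion coefficient fit. Includes a parameter-sweep driver and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
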