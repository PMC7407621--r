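Package: evbscreen
Title: Empirical Valence Bond Free-Energy Profiles and Enzyme Variant
    Screening Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale reactive-simulation and screening toolkit built
    around the two-state empirical valence bond (EVB) model of a proton
    transfer reaction. Provides diabatic and adiabatic energy/force
    evaluation, Langevin/Berendsen leapfrog dynamics in a restrained
    solvent droplet, free energy perturbation/umbrella sampling profiles
    on the energy-gap coordinate with replicate statistics and reference
    calibration, linear-response electrostatic group decomposition,
    donor-acceptor geometry and Daura clustering of conformational
    ensembles, Michaelis-Menten kinetics with Eyring transition-state
    conversions and cosolvent extrapolation, and variant-table screening
    analytics (fold ranges, enhancement counts, geometry-barrier
    correlations). Includes seeded synthetic-data generators for toy
    reactive systems, noisy rate profiles, and variant tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
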