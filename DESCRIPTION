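Package: iknm
Title: Tissue-Scale Diffusion Analysis of Interkinetic Nuclear Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models interkinetic nuclear migration (IKNM) in pseudostratified
    neuroepithelia such as the early zebrafish retina as a tissue-scale
    diffusion process. Provides a seeded synthetic generator of 3-D nuclear
    tracks with apical divisions and exponential population growth, track
    geometry and kinematics (apicobasal coordinates, cycle-normalized speeds,
    neighbour correlations, mean squared displacement), radial concentration
    profiles with a positional-uncertainty error model, an exact eigenfunction
    solution of linear diffusion in a spherical shell with exponential apical
    influx, a conservative solver for the nonlinear (lattice-gas) diffusion
    equation with a maximum packing concentration, minimal chi-square
    estimation of the effective diffusion constant with effective-variance
    errors, biophysical interpretation (Stokes-Einstein, membrane-tube drag,
    stochastic force strength, close packing), equilibrium cell-membrane
    shapes from Helfrich energy minimization, and Langevin simulations of
    single nuclei with crowding-dependent noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
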