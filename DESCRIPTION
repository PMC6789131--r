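Package: thermokin
Title: Local-in-Time Kinetic Analysis of Vibrational Energy Transport in
    Biomolecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of transient heating simulations or experiments on
    peptides and other biomolecules. Fits time-dependent residue-to-residue
    energy-transfer rate constants to per-residue kinetic-energy trajectories
    by a non-negativity-constrained master-equation inversion, then
    characterises transport: pairwise heat fluxes against effective
    temperature gradients, effective diffusivities and conductivities by
    transport regime, ballistic zero-gradient offsets, and Arrhenius
    free-energy barriers from the temperature dependence of fluxes. Includes
    synthetic trajectory generators (a master-equation forward simulator with
    a transient-heater protocol, and a nonlinear-lattice surrogate) so the
    full pipeline is testable by parameter recovery without molecular
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
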