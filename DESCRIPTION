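Package: thermorad
Title: Hybrid Cellular-Automaton Simulation of Radiotherapy and
    Hyperthermia Response In Vitro
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth of adherent cell monolayers and their
    response to ionizing radiation, hyperthermia, and combined fractionated
    treatment schedules with a lattice-based hybrid cellular automaton.
    Individual cells progress through the G1/S/G2/M cycle with normally
    distributed cycle durations, divide into free neighbouring voxels, and
    enter reversible quiescence (G0) under contact inhibition. Clonogenic
    survival is computed with the AlphaR dose-response model (a
    linear-quadratic arm below a threshold dose, single-exponential above),
    heat exposures are summarized as CEM43 thermal dose, and
    thermo-radiosensitization is modelled as a linear increase of the
    radiation alpha coefficient with thermal dose. Radiation-induced death
    is delayed: doomed cells keep proliferating, may undergo mitotic
    catastrophe to giant or senescent phenotypes, and die after an
    exponentially distributed delay. Includes replicate-ensemble growth
    curves, confidence-bound envelope runs, fractionation sweeps, and
    grid-search calibration of the delayed-death parameters against
    reference growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
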