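Package: gnrtherm
Title: Photothermal Therapy Simulation in Layered Skin with Gold Nanorods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsed-laser photothermal therapy of a skin tumor loaded
    with gold nanorods. Couples voxel-based Monte Carlo photon transport
    (Henyey-Greenstein scattering, weighted absorption, Russian roulette) through
    a four-layer skin stack to an explicit finite-difference heat-conduction
    solver with harmonic-mean interface conductivities and pulsed
    heating/cooling laser schedules. Treatment quality is quantified by the
    apoptosis retention ratio of the tumor, the thermal hazard retention value
    of the surrounding normal tissue, and their quotient, the effective
    apoptosis retention ratio; an exhaustive condition sweep selects optimal
    laser power and duty cycle per treatment time.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
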