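Package: ratgait
Title: Neuromusculoskeletal Simulation of Rat Walking and Trotting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-dynamic simulation of rat locomotion in the sagittal
    plane. Couples an eleven-link planar skeleton (trunk, two-link
    forelimbs, three-link hindlimbs) with 26 Hill-type muscles, a
    two-layer spinal central pattern generator built from four coupled
    phase oscillators and muscle-synergy pulse trains, and delayed
    posture and speed regulators acting on stance limbs. Gait (walk or
    trot) is selected by a single ipsilateral phase offset, and speed is
    modulated by the extension-phase fraction of the gait cycle.
    Includes per-cycle energetics: positive and negative muscle work,
    stride length, cost of transport and its decomposition into synergy,
    posture and speed contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
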