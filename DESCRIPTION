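Package: ntpflow
Title: Channel Geometry Profiling and Ligand Diffusion Analysis for
    Polymerase Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytics for substrate-loading studies of multi-subunit
    polymerases. Implements a pathway-exploration algorithm that traces the
    most central axis of a protein channel by iteratively maximizing the
    clearance from surrounding atoms, and extracts minimal-radius profiles
    of the channel along that axis per trajectory frame. Provides
    macro-region occupancy analysis of multi-ligand diffusion trajectories
    (binding propensities, transition graphs, partial/complete loading and
    exit event detection) and per-base-pair Watson-Crick hydrogen-bond
    melting classification with time-fraction summaries, optionally
    stratified by ligand state. A synthetic-data module generates channel
    phantoms, jump-process diffusion trajectories, and base-pair
    distance series with known ground truth so every analysis stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
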