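Package: allokin
Title: Rare-Event Detection, Kinetic Modelling and Information-Theoretic
    Allostery Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for protein(-ligand) molecular dynamics
    trajectories built around three stages: detection of rare conformational
    events by non-negative matrix factorization of residue-contact time
    series (the RED protocol), kinetic modelling of collective-variable
    dynamics by time-lagged independent component analysis, Markov state
    models and transition path theory, and quantification of allosteric
    communication between structural motifs with Gaussian
    configurational-entropy measures (total correlation, coordination
    information and mutual coordination information). Includes a
    synthetic-trajectory generator that plants contact-pattern events,
    Gaussian displacement networks and Markov-chain collective variables
    with exact ground truth, so that every stage can be validated against
    closed-form or brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
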