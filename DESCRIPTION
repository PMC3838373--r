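Package: stickleg
Title: Neuro-Mechanical Simulation of Stopping and Starting of Stepping in an
    Insect Leg
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a stick-insect middle leg as three coupled
    neuro-muscular systems (protractor-retractor, levator-depressor,
    extensor-flexor), each with a half-centre central pattern generator,
    inhibitory interneuron relays, fast and slow motoneuron pools, and
    antagonistic muscle pairs with fast and slow fibres.  Slow fibres carry a
    residual stiffness gated by common inhibitory motoneurons; muscle-fibre
    recruitment sets stationary joint angles.  Central stop and start
    commands act purely on motoneuron-level gates, driven by joint-angle and
    angular-velocity sensory signals, while the pattern generators run
    autonomously.  Provides a fixed-step event-gated simulator, trace and
    event logs, phase extraction, convergence analysis, experiment and
    fixture generators, and a configuration layer packaging the published
    muscle parameter tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
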