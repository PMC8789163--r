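Package: predgait
Title: Muscle-Driven Predictive Simulation of Walking by Direct Collocation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A planar muscle-driven musculoskeletal simulator (Hill-type
    muscles with an adjustable Achilles-tendon stiffness, a passively
    actuated metatarsophalangeal toe joint, smooth Hunt-Crossley
    foot-ground contact, and a smoothed Bhargava metabolic energy model)
    wrapped in a direct-collocation (third-order Radau) optimal-control
    pipeline that generates de novo periodic gaits at a prescribed speed.
    Includes model-variant studies (locked toes, triceps-surae tendon
    stiffness sweeps, mass redistribution and contact-sphere height),
    gait evaluation metrics (cost of transport, stance RMSE, vertical
    ground-reaction-force peaks), a synthetic reference-gait generator,
    motion-storage file input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
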