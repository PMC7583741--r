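Package: copsense
Title: Plantar Pressure Sensor Placement by Maximum-Entropy Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Designs sparse plantar pressure sensor layouts that reproduce the
    center-of-pressure (COP) trajectory of full-resolution plantar pressure
    videos. Provides the preprocessing pipeline for stance-phase pressure
    videos (splitting, representative selection, border cropping,
    force-conserving downsampling), a COP-fit reward with exact per-step
    reward redistribution, a discrete sensor-placement environment, a
    Soft Actor-Critic agent for discrete actions with clipped double
    Q-learning and Polyak-averaged targets, population-based training of the
    entropy temperature, synthetic pressure-video generators, and a
    brute-force placement oracle for small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
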