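Package: trajmodes
Title: Transport-Mode Analysis of Single-Particle Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mean-squared-displacement (MSD) analysis of 2D single-particle
    trajectories from live-cell tracking experiments. Computes time- and
    ensemble-averaged MSDs, fits the four canonical transport-mode models
    (normal diffusion, active transport, anomalous subdiffusion, confined
    diffusion), classifies every trajectory position into a transport mode
    with a rolling analysis window and a minimum-segment rule, and derives
    mobility statistics: mode proportions, active-segment velocities,
    per-mode diffusion constants, segment lengths, rapid-transport
    fractions, displacement probability densities, and Stokes-Einstein
    viscosities. Includes a labelled trajectory simulator (Brownian,
    active, fractional-Brownian subdiffusive, and confined motion, with
    mode switching, localization noise, and stage drift) so that every
    analysis stage can be validated by parameter recovery, plus readers
    and writers for the table formats exported by common tracking
    software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
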