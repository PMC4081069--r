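Package: forcemelt
Title: Simulation and Analysis of Force-Induced DNA Melting in Optical-Tweezers Pull-Relax Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to synthesize and analyse force-versus-trap-position
    trajectories from constant-velocity optical-tweezers experiments on short
    designed DNA duplexes. A kinetic Monte-Carlo simulator reproduces the
    phenomenology of force-induced peeling, internal melting and the B-to-S
    overstretching transition (abrupt rips with hysteretic rezipping, bistable
    hopping intermediates, gradual non-cooperative melting) with full ground
    truth. The analysis side provides rip/zip change-point detection, linear
    branch fitting, reaction-extent computation, two-state (midpoint force and
    cooperative length) and three-state (intermediate population) equilibrium
    fits, hysteresis classification and ensemble reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
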