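Package: windhover
Title: Wind Tunnel Flow Synthesis and Windhover Flight Analysis
Version: 0.1.0
Authors@R:
    person("Windhover", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for studying windhovering (station-keeping) bird flight in
    an orographic-updraft wind tunnel. Synthesises replicated atmospheric
    turbulence with a von Karman longitudinal spectrum, models ramp-induced
    updraft fields, characterises probe velocity records (turbulence
    intensity, spectral slope, integral length scale), assembles and
    interpolates flow maps, detects windhover epochs in motion-capture
    trajectories, associates hovers with local flow conditions, and computes
    glide-envelope coverage from lift-to-drag tables. A synthetic-data module
    with ground truth makes every pipeline stage testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
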