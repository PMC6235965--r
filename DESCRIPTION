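Package: activeload
Title: Active Loading Control and Signal Processing for Single-Cell
    Microfluidic Mass Sensors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in-silico implementation of optically triggered "active
    loading" for single-cell microfluidic measurement channels. Provides the
    four-state (load/seek/queue/reject) fluidic controller driven by image
    region-of-interest events, an event-driven stochastic simulator of the
    two-channel device with Poisson particle arrivals, closed-form passive and
    active throughput theory as a function of sample concentration, synthetic
    bright-field frame generation with geometric particle detection and
    debris/doublet rejection, the suspended microchannel resonator (SMR)
    signal chain that converts resonant-frequency traces into transit times,
    buoyant masses and mass accumulation rates (MAR), and group-level
    statistics for drug-versus-control comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
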