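Package: tactsim
Title: Electromechanical Circuit Simulation of Tactile Afferent Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the spiking responses of the three major classes of
    cutaneous tactile afferents (SA1, RA1 and Pacinian) to skin-indentation
    waveforms using an electromechanical circuit model: a two-channel
    (low-pass + band-pass) receptor filter, a rectifier, a linear
    mechanotransducer with diode-style thresholding, and a pulse-frequency
    -modulation spike synthesizer that superposes a configurable action
    -potential template at each carrier cycle. Includes stimulus generators
    (sinusoids, ramp-and-hold indentations, amplitude staircases), a
    synthetic firing-rate dataset generator, a quasi-Newton training
    procedure that fits the filter parameters to firing-rate surfaces, and
    evaluation tools: vibrotactile frequency-threshold curves, ISI-distance
    spike-train comparison and jitter-based timing-precision analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
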