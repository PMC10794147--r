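Package: mfsa
Title: Design and Nucleation Kinetics of Multifarious Tile Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and simulating multifarious DNA tile
    self-assembly systems whose nucleation kinetics classify high-dimensional
    concentration patterns. Builds shared-tile systems from fully unique
    multi-shape designs by constrained stochastic merging under self-healing
    and second-order proofreading criteria; estimates shape-selective
    nucleation rates from concentration patterns with a stochastic greedy
    pathway model and a window-based proxy; trains pixel-to-tile maps by hill
    climbing so grayscale images are classified by which structure nucleates;
    integrates a winner-take-all competitive nucleation/growth model over
    temperature anneals; and analyses fluorescence quench traces (quench
    times, growth times, selectivity fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
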