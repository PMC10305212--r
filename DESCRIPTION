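Package: monofilm
Title: Thermodynamic Analysis of Langmuir Monolayer Isotherms and Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of Langmuir monolayer
    experiments at the air-water interface: extraction of characteristic
    surface pressure-area isotherm parameters (liftoff area, limiting area,
    collapse point), the additivity rule for limiting areas of mixed films,
    excess Gibbs energy and Gibbs energy of mixing of multicomponent
    monolayers, the compressional elastic modulus with phase-transition
    detection, and single-exponential fitting of constant-area surface
    pressure relaxation traces. Includes a synthetic-data generator that
    builds isotherms from prescribed elasticity profiles, mixtures with known
    non-ideality, and relaxation traces, so every analysis stage has a
    closed-form or round-trip oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
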