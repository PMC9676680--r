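Package: venacoustics
Title: Coupled Hemodynamic and Vibro/Hydroacoustic Simulation of Venous
    Pulsatile Tinnitus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic pipeline for studying the acoustic
    sources of venous pulsatile tinnitus in the transverse-sigmoid sinus
    system. Generates a parametric two-dimensional curved venous conduit with
    named anatomical landmarks and a layered wall-composition map (sigmoid
    plate, dura mater, vascular wall, with a dehiscence patch), synthesizes a
    periodic pulsatile inlet waveform, solves transient incompressible laminar
    flow with a staggered-grid projection method, computes hydroacoustic
    sources via the incompressible Lighthill analogy and solves per-frequency
    Helmholtz problems at virtual microphones, models flow-forced displacement
    of layered wall patches and the radiated vibroacoustic field, and provides
    band-limited SPL/A-weighted metrics, sonification, and spectro-temporal
    analysis of paired ear-canal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
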