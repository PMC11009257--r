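Package: cowflow
Title: Lumped-Parameter Circle of Willis Hemodynamics and Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pulsatile zero-dimensional (lumped-parameter) blood flow
    simulation on circle of Willis (CoW) vascular networks, aimed at
    anterior communicating artery aneurysm (AComA) analysis. Computes
    Hagen-Poiseuille segment resistances (including tapered vessels),
    solves nodal pressures and segment flows under prescribed inlet
    waveforms with zero-gauge outlet pressures, derives cycle-level wall
    shear stress statistics (TAWSS, systolic/diastolic WSS, OSI, RRT),
    performs complete-to-half model surgery, and implements a two-step
    resistance-ratio rule for choosing between complete and half CoW
    models. Ships a seeded synthetic generator of patient-like CoW
    networks and inlet waveforms for testing without angiographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
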