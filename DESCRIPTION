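Package: meawave
Title: Extracellular Electrophysiology of Cell Populations on Large-Area
    Multi-Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of single-channel extracellular current
    recordings from cell populations cultured on large-area gold
    multi-electrode arrays, as used to monitor prostate-cancer (PC-3) cell
    cultures.  Provides an electrode-electrolyte equivalent-circuit
    measurement model (double-layer capacitance coupling and transimpedance
    read-out), a ground-truth synthetic recording generator covering
    medium-only baseline, asynchronous-sporadic and quasi-periodic biphasic
    spiking regimes and a three-phase calcium-channel inhibition protocol,
    threshold-based spike detection with biphasic pairing, regime
    segmentation and spike statistics, traveling-wave speed estimation from
    biphasic lobe separations, inhibition block/recovery calls, and
    growth/viability normalisation arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
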