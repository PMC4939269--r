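Package: geobattery
Title: Porewater Geochemistry Diagnostics for Long-Distance Electron
    Transfer by Cable Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to diagnose long-distance electron transfer (LDET) by
    sulfur-oxidizing cable bacteria from depth-resolved porewater
    microprofiles of oxygen, pH and sulfide in sediment columns.
    Implements diffusive flux calculation from concentration gradients
    (Fick's first law with porosity), carbonate-system speciation and
    alkalinity at constant dissolved inorganic carbon, cathodic proton
    consumption from convergent alkalinity fluxes around the oxic pH
    maximum, conversion to electric current density via the Faraday
    constant, cathodic oxygen consumption, theoretical sulfate recycling,
    and ATP-based cell density estimates.  Includes a one-dimensional
    steady-state reaction-diffusion simulator of the sediment geobattery
    (spatially separated, current-coupled redox half reactions) for
    generating synthetic profiles with known ground truth, and T-RFLP
    fingerprint utilities (in-silico terminal restriction fragment
    prediction, fragment clustering, peak normalization and replicate
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
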