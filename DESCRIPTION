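Package: valvefatigue
Title: Fatigue Life and Tear Propagation Analysis for Bioprosthetic Valve Leaflets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the durability of bioprosthetic (tissue)
    heart valve leaflets from stress time-histories at a leaflet integration
    point. Implements load-spectrum simplification, four-point rainflow cycle
    counting with half-cycle bookkeeping, Gerber mean-stress correction to
    pulsatile-equivalent amplitudes, Basquin S-N life, and Miner linear damage
    accumulation, reporting expected life in cardiac cycles and calendar time
    at a given heart rate. Also provides an elliptical-tear growth predictor
    combining a strain-energy-density (Glinka) notch-stress solve with
    Paris-law crack-growth superposition, neo-Hookean material parameter
    helpers, and a seeded generator of cardiac-cycle-shaped stress spectra for
    testing the pipeline without fluid-structure-interaction output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
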