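Package: dntbattery
Title: Hazard Characterization for a Human DNT In Vitro Testing Battery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Concentration-response analysis for a human cell-based
    developmental neurotoxicity (DNT) in vitro testing battery. Fits
    variable-slope sigmoidal and bell-shaped concentration-response curves,
    derives benchmark concentrations (BMC) with bootstrap confidence
    intervals, classifies DNT hits as specific, borderline or unspecific
    against paired viability and cytotoxicity endpoints, determines each
    compound's most sensitive endpoint, scales potencies to ToxPi-style
    slice scores with hierarchical profile clustering and a merged
    MSE/ToxPi prioritization ranking, and relates hazard to human
    biomonitoring exposure via molarity and daily-intake conversions.
    Includes a ground-truth-labelled synthetic screen generator emulating
    the battery's plate designs so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, DoseResponse, Pharmacogenetics, StatisticalMethod
RoxygenNote: 7.3.3
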