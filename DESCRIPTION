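Package: ddcqa
Title: Difference-Detail-Curve Assessment of Low-Contrast CT Image Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing low-contrast detectability in computed
    tomography with a modular body phantom carrying 30 randomly positioned
    contrast rods (six diameters, five nominal contrasts over a ~60 HU epoxy
    base). The package models the phantom geometry and rod materials,
    simulates CT scans of it with dose-scaled Gaussian noise and an optional
    kV-dependent contrast response, verifies rod contrasts automatically via
    template registration, morphological ROI erosion and region statistics,
    converts observer click sessions into difference detail curves (DDCs),
    fits the log-linear DDC model with sum-to-zero observer-bias terms, and
    quantifies the robustness of the fitted parameters by bootstrap
    resampling over observers. A command-line interface ties the stages into
    a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
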