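Package: copsebox
Title: COPSE-Style Biogeochemical Box Modelling of Neoproterozoic Oxygenation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A carbon-oxygen-phosphorus-sulphur-nitrogen (COPSE-style) global
    biogeochemical box model with a coupled ocean-sediment strontium isotope
    system, configured for the late Neoproterozoic. Provides stiff ODE
    integration of the coupled geochemical cycles, steady-state response
    surfaces over tectonic degassing and uplift forcings, Monte-Carlo
    parameter-uncertainty ensembles with seeded degassing-path sampling,
    synthetic pseudo-proxy record generation, and least-squares secular trend
    regression of isotope records (raw and binned). The headline application
    is quantifying the atmospheric O2 rise across the Ediacaran driven by
    increased tectonic CO2 and sulphur degassing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
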