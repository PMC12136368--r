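Package: sebalwp
Title: Surface Energy Balance Evapotranspiration and Crop Water Productivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieves crop evapotranspiration (ET) from Landsat-like
    multispectral and thermal scenes with the SEBAL surface energy balance
    (net radiation, soil heat flux, anchor-pixel-calibrated sensible heat
    with Monin-Obukhov stability iteration, latent heat residual and
    evaporative fraction), validates daily ET against the FAO-56
    Penman-Monteith reference equation, upscales the evaporative fraction
    between overpass dates to seasonal ET, and maps crop water productivity
    (kg of grain per cubic metre of water consumed) with zonal statistics
    and correlation analysis against elevation, temperature and
    precipitation.  A seeded synthetic-scene generator with known
    evaporative-fraction ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
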