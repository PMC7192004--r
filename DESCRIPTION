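Package: canopyflux
Title: Vineyard Canopy Structure from Photogrammetric Point Clouds and
    Two-Source Energy Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts per-grid-cell structural and spectral canopy metrics
    (TIN volume, 3D surface area, projected area, height, fractional cover)
    from georeferenced photogrammetric point clouds of trellised vineyards
    with an inter-row cover crop, partitions radiometric temperature into
    soil and canopy components from the per-cell NDVI-temperature scatter,
    evaluates published leaf-area-index models on the normalized metrics,
    and drives a two-source energy balance (TSEB-2T) with series resistances
    and Monin-Obukhov stability iteration to per-cell sensible and latent
    heat fluxes.  Includes a parametric synthetic vineyard scene generator
    with analytic per-cell truth, eddy-covariance Bowen-ratio closure
    forcing, and model evaluation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    interp,
    RANN,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
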