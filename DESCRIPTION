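Package: firemapr
Title: Automatic Burned-Area and Fire-Severity Mapping from Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Maps wildfire burned areas and fire severity from co-registered
    pre- and post-fire multispectral surface-reflectance rasters of
    SuperDove-class sensors (8 visible/NIR bands, no SWIR). Computes nine
    vegetation indices and their pre-minus-post differences, screens indices by
    masked mean difference, segments burned from unburned pixels with a
    self-contained bisecting k-means in a two-dimensional index-difference
    space, stratifies burned pixels into four ordered severity classes with
    k-means, and estimates slope-corrected burned surface in hectares using a
    DEM (Horn slope, per-pixel 1/cos(slope) weights). Includes a lightweight
    GeoTIFF reader/writer, GeoJSON polygon rasterization, a synthetic-scene
    generator with analytic ground truth for end-to-end validation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    mgcv,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
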