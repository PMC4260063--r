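Package: appdens
Title: Adaptive Spatial Sampling and Kernel Density Surfaces for
    Geosocial App Users
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses an adaptive field protocol for
    estimating the spatial density of geosocial networking app users
    from a small number of sampling stops.  At each stop the k nearest
    user profiles (or all profiles within a maximum radius) are
    captured, the observed radius becomes the step to the next stop,
    and per-stop counts are standardized to a common reference area.
    Weighted kernel density estimation turns the stops into raster
    surfaces of users per square mile, stratified by race and age
    group, and map-algebra operations (difference, ratio, and a
    mean-plus-two-standard-deviations indicator difference) compare
    subgroup surfaces to highlight areas dense in specific
    subpopulations.  Includes a marked point-process generator for
    synthetic user populations, plain-text readers and writers (CSV,
    GeoJSON, ESRI ASCII grid), and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    mgcv,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
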