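Package: ecotone
Title: Climate Transition-Zone Delimitation from Vegetation and Environmental Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delimits the transition zone (ecotone) between two climate zones
    from co-registered environmental raster covariates and the mapped
    occurrences of paired indicator vegetation types. Screens covariates per
    vegetation pair with the variance-decomposition q-statistic (factor
    detector) with a permutation significance test, builds a per-pair index
    system by thresholded top-k selection, maps each pair's two-zone
    partition with a support vector machine, extracts the inter-zone boundary
    polylines, composes several pairs' boundaries into a transition-zone band
    with width statistics, characterizes the resulting three zones by zonal
    sampling and three-strata q-statistics, and validates boundaries against
    graded quadrat survey counts. Includes a synthetic-landscape generator
    with known boundary geometry so the whole workflow is testable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
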