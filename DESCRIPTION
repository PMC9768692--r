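Package: geoparmap
Title: Geospatial Parametric Mapping of Sparse Point Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological inference on sparse geospatial point data.
    Point observations are distributed over a regular raster with an
    isotropic Gaussian kernel at one or more spatial scales, a general
    linear model is fitted independently at every grid cell, and contrast
    t maps are thresholded with voxel-level family-wise error correction
    based on random field theory. Includes a synthetic validation suite
    built on Koch-snowflake region layouts with parameterised noise and
    interaction effects, segmentation-based recovery scoring, a
    coverage-based smoothing-scale selection rule, and standardisation of
    external kriging predictions for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    mgcv,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
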