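Package: landres
Title: Landscape Resistance Surfaces and Effective Distance Models for
    Landscape Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a-priori landscape-genetic modelling on raster
    landscapes: construction of per-species resistance surfaces (uniform
    null, tree-cover, habitat-suitability and expert-opinion land-cover
    models), pairwise effective distances between sampling sites by
    least-cost path and by circuit-theory effective resistance on 4- or
    8-connected grid graphs, identification and validation of
    isolation-by-distance null models including the bounded-grid edge
    effect, comparison of correlated distance models with an
    independent-pair bootstrap, and aggregation of expert-opinion mobility
    estimates into resistance tables with variance decomposition. A
    synthetic-landscape generator provides land-cover rasters, site sets,
    habitat-suitability surfaces and expert panels with known structure so
    that every pipeline stage is testable without external GIS layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    lme4,
    mgcv,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
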