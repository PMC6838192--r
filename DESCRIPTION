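Package: landres
Title: Landscape Resistance Optimization and Isolation-by-Resistance Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape genetics: Weir-Cockerham F_ST estimation from
    diploid microsatellite genotypes, construction of landscape resistance
    surfaces (categorical reclassification, Monomolecular and Ricker
    transformations), circuit-theory effective resistance and cumulative
    current maps on raster grids, maximum-likelihood population-effects (MLPE)
    mixed models for pairwise genetic distances, genetic-algorithm optimization
    of resistance-surface parameters, and bootstrap AICc model selection across
    candidate surfaces. Includes a synthetic-data generator that reproduces the
    full generative structure (spatially autocorrelated landscapes,
    Balding-Nichols genotypes, MLPE-structured genetic distances) so the whole
    inference chain can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
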