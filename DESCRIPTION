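Package: ecotone
Title: Gradient Flattening and Loss of Morphological Divergence Along
    Rainforest-Savanna Ecotones
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the steepness of a tree-cover gradient from
    raster data, test for region-dependent gradient slope with an ANCOVA on
    latitudinal band means, and test whether phenotypic divergence between
    rainforest and ecotone bird populations along the gradient has been
    lost. Implements allometric size correction by log-log residuals,
    covariance-structure-gated principal components analysis (equality and
    proportionality likelihood-ratio tests in the Flury hierarchy),
    Wilcoxon rank-sum divergence tests under Dunn-Sidak family-wise
    control, a habitat-stratified bootstrap null for the absence of
    divergence at the individual and population level, sample-size-weighted
    phenotype-on-tree-cover regressions projected over rasters, and a
    synthetic-data module that emulates satellite tree-cover rasters, field
    sites, and contemporary and historical morphology tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
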