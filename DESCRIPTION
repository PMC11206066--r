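Package: elevassembly
Title: Community Assembly Analysis of Soil Microbiomes Along Elevation Gradients
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting deterministic and stochastic assembly of
    soil bacterial communities sampled along an elevation gradient. Implements
    Levins niche-breadth classification of OTUs into habitat generalists,
    neutral taxa and specialists against count-preserving quasiswap
    permutation nulls; Sloan neutral community model fitting with migration
    rate estimation and binomial prediction bands; C-score co-occurrence
    analysis with fixed-margin null models and standardized effect sizes;
    multivariate regression trees partitioning samples into elevation bands;
    redundancy analysis, envfit-style permutation tests and three-block
    variance partitioning of environmental drivers; and a synthetic-data
    generator with known ground truth (neutral Dirichlet-multinomial backbone,
    planted generalists and specialists, elevation-structured covariates) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
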