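Package: phaseOrder
Title: Estimation and Comparison of Circular Temporal Orders of Oscillatory Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for estimating the common temporal
    (circular) order among the phase angles of oscillatory genes measured in
    multiple experiments, and for testing whether that order is conserved
    across experimental groups (e.g. species). Phase angles are modelled as
    von Mises observations around gene-specific mean directions; the common
    cyclic order is estimated by minimizing a weighted mean sum of circular
    errors via circular isotonic regression, an asymmetric travelling-salesman
    reformulation solved exactly by Held-Karp dynamic programming at small
    panel sizes, and a circular local minimization refinement. Conservation of
    order across groups is tested with an ANOVA-like statistic and a weighted
    resampling scheme; partial orders with bootstrap confidence coefficients
    and a forward gene-selection procedure are provided, together with a
    synthetic-data generator and operating-characteristic harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, GeneExpression, CellCycle, TimeCourse
RoxygenNote: 7.3.3
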