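Package: habicomp
Title: Knowledge-Driven and Occurrence-Driven Habitat Suitability Modelling and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares habitat-suitability surfaces for grassland pest
    risk mapping from two modelling families on a shared raster grid: a
    knowledge-driven multi-criteria branch (expert 1-5 suitability grading,
    analytic hierarchy process weights with consistency checking, TOPSIS
    ideal-solution ranking, and ordered weighted averaging across decision
    attitudes) and an occurrence-driven branch (pseudo-absence sampling, a
    ridge-stabilised logistic baseline, repeated stratified cross-validation,
    and a TSS-weighted ensemble). Includes a synthetic-landscape simulator with
    known ground truth, raster harmonisation and terrain/distance
    preprocessing, occurrence thinning and collinearity screening, and the
    cross-framework comparison toolkit: AUC and true-skill-statistic scoring,
    CDF (percentile) normalisation, exact Fisher-Jenks classification with
    empirical thresholds, area proportions, occurrence hit rates, agreement
    maps and Jaccard overlap indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    geosphere,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'io.R'
    'rng.R'
    'synthetic-landscape.R'
    'geo-prep.R'
    'grading.R'
    'mca-ahp.R'
    'mca-surfaces.R'
    'occurrence-models.R'
    'evaluation.R'
    'compare.R'
    'habicomp-package.R'
    'pipeline.R'
    'show-methods.R'
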