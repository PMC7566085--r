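Package: phenomod
Title: Connected Gene Modules Associated with Continuous Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies connected subnetworks of genes whose somatic
    alterations are associated with a continuous per-sample phenotype such
    as drug sensitivity. Candidate modules maximize a connected set cover
    objective over a binary gene-by-sample alteration matrix, optionally
    penalizing overlapping (non mutually exclusive) alterations, with genes
    associated with increased and decreased sensitivity selected
    simultaneously under combined or separate connectivity models. Module
    significance is assessed by phenotype permutation and maximal
    significant modules are reported. Includes an exact branch-and-bound
    optimizer, a brute-force verification oracle, a planted-module
    simulator, and evaluation utilities (network distance to drug targets,
    three-group ANOVA validation, opposite-direction drug-pair screening).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'objective.R'
    'solver.R'
    'significance.R'
    'simulate.R'
    'evaluate.R'
    'io.R'
    'phenomod-package.R'
    'pipeline.R'
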