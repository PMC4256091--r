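Package: phewasKit
Title: Phenome-Wide Association Scans with Cross-Survey Replication
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phenome-wide association studies (PheWAS) in
    multi-survey epidemiologic collections. Runs unadjusted additive-model
    single-SNP linear and logistic regression scans across many phenotype
    measurements, stratified by self-reported race-ethnicity; harmonizes
    survey-specific phenotypes into phenotype classes (log(y+1)
    transformation, A-versus-not-A binarization of categoricals, pooled
    combined-survey variables); applies a seven-criterion cross-survey
    replication filter (both surveys, p < 0.01, allele frequency > 0.01,
    n > 200, same stratum, class and direction of effect); classifies
    retained results against a prior-association catalog as replicated,
    related or novel; detects pleiotropy and cross-stratum generalization;
    reports phenotype correlations with clustered heatmap export; and
    builds SNP-gene-pathway association networks pruned to multi-SNP
    components. A synthetic two-survey data generator with Hardy-Weinberg
    genotypes, planted additive effects, correlated phenotype blocks and
    missingness makes every stage testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, yaml, jsonlite
Suggests: testthat (>= 3.0.0), vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
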