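Package: htnprs
Title: Multi-Ethnic Polygenic Risk Scores for Hypertension Prevalence and
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of multi-ethnic polygenic risk
    scores (PRS) for hypertension from GWAS summary statistics.  Implements
    clump-and-threshold PRS construction over a tuning-parameter grid,
    tuning-parameter selection by minimizing the coefficient of variation of
    effect estimates across kinship-disjoint subsets of a training cohort,
    unweighted combination of trait-specific scores (PRSsum), blood-pressure
    phenotyping (prevalent, longitudinal and incident hypertension),
    association analytics (logistic and kinship mixed models, AUC on
    unrelated individuals, correlated Cochran's Q, decile analyses), and
    age-dependent hypertension risk trajectories from random-intercept
    generalized linear mixed models.  A self-contained simulator generates
    multi-ancestry genotypes with linkage disequilibrium and relatedness,
    correlated blood-pressure genetic effects, discovery summary statistics,
    and longitudinal blood-pressure phenotypes, so every stage is testable
    without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    lme4,
    Matrix,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml
Config/testthat/edition: 3
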