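Package: wSuStaIn
Title: Subtype and Stage Inference for Regional Brain Atrophy from
    Control-Referenced w-Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A data-driven subtyping-and-staging pipeline for regional
    brain-volume cohorts on the ALS-FTD spectrum. Regional volumes are
    normalized to covariate-adjusted w-scores against healthy controls,
    reduced to stable anatomical clusters by bootstrap consensus
    clustering (BASC), and modelled with a piecewise-linear w-score
    Subtype and Stage Inference (SuStaIn) mixture of event sequences.
    Includes Metropolis-Hastings uncertainty estimation over sequence
    permutations, cross-validated selection of the number of subtypes
    (CVIC), per-subject subtype/stage assignment with a stage-0
    normal-appearing rule, longitudinal stability and annualized stage
    change metrics, the cohort group-comparison statistics layer, and a
    fully seeded synthetic-cohort generator with ground truth for
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
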