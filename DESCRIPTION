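Package: ClusterMokken
Title: Two-Step, Test-Guided Mokken Scale Analysis for Nonclustered and
    Clustered Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mokken scale analysis for ordinal questionnaire data collected
    under simple random sampling or two-stage cluster sampling. Provides
    point estimates of item-pair, item, and total scalability coefficients
    together with one-level (simple random sample) and two-level
    (cluster-robust) standard errors obtained from an influence-function
    delta method, a cluster-bootstrap oracle, Mokken's Delta tests, Wald and
    range-preserving z tests and confidence intervals, the classic automated
    item selection procedure (AISP) and its test-guided variant (T-AISP)
    with sequential Bonferroni correction, one-way ANOVA intraclass
    correlation diagnostics, a two-step test-guided workflow that ties these
    together, and a multilevel graded response model simulator with
    population-level scalability oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'itemScores.R'
    'clustered.R'
    'maxCovariance.R'
    'scalability.R'
    'uncertainty.R'
    'testing.R'
    'selection.R'
    'synthetic.R'
    'swmdk.R'
    'workflow.R'
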