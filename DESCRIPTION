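Package: TopoMed
Title: Topological Properties of Functional Brain Networks and Their
    Mediation of Belief-Cognition Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking ordinal survey measures of parental belief
    strength to multiscale topological properties of resting-state
    functional brain networks and to cognitive task scores. Provides
    connectivity estimation from parcel time series (peak
    cross-correlation and mutual information), population-based
    thresholding, global and nodal graph-topology metrics (efficiency,
    modularity, clustering, small-worldness, natural connectivity,
    spectral stability, eigenvector centrality), covariate-adjusted
    standardized regression with Sobel mediation and simple-slope
    moderation, dual false discovery rate control, propensity-style site
    adjustment, split-sample validation by CV(RMSE), survey
    summarization, and a synthetic cohort generator that plants the
    statistical structure the analysis assumes so that the entire
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
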