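Package: dmnmetrics
Title: Person-Level Summary Metrics and Norms for Default Mode Network
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes person-level summary metrics of functional brain
    network connectivity from parcel-averaged BOLD time series: average
    Fisher-Z connectivity over the default mode network and its anterior
    and posterior-to-anterior sub-networks, together with weighted graph
    alternatives (global clustering coefficient and characteristic path
    length on proportionally thresholded graphs). Includes motion and
    signal-intensity frame censoring with temporal-mask expansion,
    nuisance residualization, band-pass filtering, data-sufficiency
    rules, reliability evaluation (quintile-split Cronbach's alpha and
    agreement intraclass correlation with confidence intervals), built-in
    normative constants stratified by age, normative z-scoring of single
    subjects, and a synthetic-data generator with block-structured
    correlations and injectable motion spikes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'parcellation.R'
    'preprocess.R'
    'connectivity.R'
    'graph-metrics.R'
    'reliability.R'
    'norms.R'
    'synthetic-data.R'
    'io.R'
    'dmnmetrics-package.R'
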