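Package: ligfish
Title: Ligand-Based Target Fishing with Multi-Conformational Pharmacophore Fingerprints
Version: 0.1.0
Authors@R:
    person("Ligfish", "Developers", email = "maintainer@ligfish.org", role = c("aut", "cre"))
Description: Tools for ligand-based target fishing in drug discovery.
    Converts 3D conformer ensembles into 3-point pharmacophore triplet
    fingerprints, merges them into modal (multi-conformational)
    fingerprints, trains ensembles of linear support vector machine and
    Bernoulli naive Bayes classifiers on labelled bioassay datasets via
    recurrent stratified resampling, calibrates raw ensemble scores into
    probability-of-activity (Pa) and probability-of-inactivity (Pi)
    estimates with confidence limits that double as an applicability
    domain filter, validates models with rank-sum AUC (Hanley/Nicholls
    standard errors), Power Metric, F-score, Matthews correlation and
    enrichment factor, and aggregates per-assay predictions into ranked
    activity classes for multi-target profiling of compound series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
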