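Package: riliMetab
Title: Metabolomic Screening, Marker-Panel Selection and Injury Triage for
    Radiation-Induced Lung Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for LC-MS pseudotargeted metabolomics of
    radiation-induced lung injury in rodent models of whole-thorax
    irradiation. Provides quality-control filtering and internal-standard
    normalization of peak-area tables, nonparametric and ANOVA differential
    screening with Benjamini-Hochberg control, NIPALS partial least squares
    discriminant analysis with variable importance in projection, orthogonal
    signal correction and Gaussian kernel PLS for dose-group triage,
    cross-tissue marker-panel selection, metabolite Pearson correlation
    networks, acylcarnitine-derived CPT1/CPT2 surrogate enzyme ratios, and a
    synthetic cohort generator that emulates the dose- and time-dependent
    study design so that every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
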