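Package: omiclink
Title: Time-Series Gene-Metabolite Association Mining
Version: 0.1.0
Authors@R: person("omiclink", "maintainers", email = "maintainers@omiclink.dev", role = c("aut", "cre"))
Description: Mines associated gene-metabolite pairs from short longitudinal
    transcriptome and metabolome matrices. Seven causality and correlation
    estimators (Pearson, Spearman, convergent cross-mapping, Granger
    causality, canonical correlation analysis, dynamic time warping and the
    cross-correlation function) score every gene against a target
    metabolite; a heuristic CAT score combines the association with the
    normalized log2 fold change between the metabolite's peak and decline
    time points, optionally adjusted by rule-based annotation bonuses.
    Includes median-of-ratios count normalization, a seeded synthetic-data
    module for offline benchmarking, a metabolite correlation network, and a
    command-line pipeline entry point.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
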