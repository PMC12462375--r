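Package: kdcurate
Title: Curation-Error Auditing and Structure-Based Binding-Affinity
    Benchmarking for Protein Heterodimer KD Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit equilibrium dissociation constant (KD) curation
    in PDBBind-style protein-protein datasets and to measure how curation
    errors degrade structure-based machine-learning prediction of
    log10(KD).  Provides a six-category curation-error taxonomy with a
    rule-based classifier, RF-score interface atom-pair features and
    Prodigy-style inter-residue contact / non-interacting-surface features,
    a Smith-Waterman sequence distance between heterodimers with
    single-linkage clustering-based cross-validation, random-forest and
    AIC-stepwise linear affinity models, and a synthetic heterodimer
    generator with planted affinities and injected curation errors so the
    whole analysis runs without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
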