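Package: gliodev
Title: Regional Brain Activity and Network Deviation Mapping for Glioma MEG Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for resting-state magnetoencephalography in
    glioma patients and healthy controls. Estimates regional neuronal
    activity as the offset of the aperiodic (1/f-like) component of the
    power spectrum, reconstructs frequency-specific functional networks
    with the phase lag index, derives binary graph metrics (local
    clustering coefficient, eigenvector centrality), standardizes regional
    values against a healthy-control cohort to obtain deviation maps,
    partitions regions into (peri)tumoral, contralateral-homologue and
    rest-of-brain areas, and runs group comparisons, spatially constrained
    spin permutation tests and within-subject linear mixed models. A
    synthetic-data generator with known aperiodic and phase-coupling
    ground truth makes every stage testable without patient recordings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
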