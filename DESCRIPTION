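Package: cryomethyl
Title: Storage-Associated Decay of DNA Methylation Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for quantifying how long-term cryopreservation of
    extracted DNA biases CpG methylation measurements. Provides robust linear
    regression of mean global methylation on storage duration, per-CpG
    differential methylation with empirical-Bayes moderated t-statistics and
    Storey q-values, a permutation null, discovery-validation replication,
    Fisher's exact enrichment of CpG-island-relation categories, reference-based
    blood cell-type deconvolution, and a synthetic-data generator that simulates
    deamination-driven decay of the methylated fraction for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
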