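Package: crscore
Title: Circadian Rhythm Score Analysis for Tumor Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-sample circadian rhythm scoring of tumor transcriptomes.
    Computes rank-based single-sample gene-set enrichment (ssGSEA) of
    clock-control and core-clock gene sets and their difference, the
    circadian rhythm score (CRS); stratifies patients at the maximally
    selected rank-statistic cutpoint and compares groups with
    Kaplan-Meier curves, log-rank tests and univariate Cox regression;
    summarizes mutation frequency, GISTIC-style copy-number calls and
    copy-number/expression coupling; screens immune-cell fractions and
    immune-checkpoint genes against the CRS; and scores compound
    perturbation signatures with a bidirectional Kolmogorov-Smirnov
    connectivity statistic.  A synthetic-data generator emulates the
    cohort structures (tumor/normal contrasts, CRS-linked survival,
    knockouts, time courses, compound libraries) so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
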