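Package: iraeab
Title: Autoantibody Microarray Analysis of Immune-Related Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for autoantigen microarray studies of
    immune-related adverse events (irAE) in checkpoint-inhibitor-treated
    cohorts.  Converts spot-level net fluorescence intensities and
    signal-to-noise ratios into antibody scores, filters antigens with
    weak signal across samples, normalizes samples against internal
    positive controls with a robust linear model, compares antibody
    scores between clinically defined patient groups with Mann-Whitney
    tests and Benjamini-Hochberg adjustment, clusters patients into
    intensity subgroups, computes baseline-to-week-6 fold changes,
    classifies ANA/RF/anti-CCP serostatus with seroconversion
    accounting, and runs Kaplan-Meier / log-rank time-to-event analyses.
    Includes a seeded synthetic-cohort generator so every stage can be
    exercised and validated without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
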