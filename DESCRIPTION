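Package: cardiomps
Title: Optical Electrophysiology Analysis for Cardiac Microphysiological Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optical action-potential and calcium-transient
    recordings from human iPSC-derived cardiac microphysiological systems (MPS)
    used in dose-escalation cardiotoxicity screening. Extracts per-beat metrics
    (APD30/50/80/90, maximum upstroke velocity, beat rate), applies Fridericia
    rate correction, quantifies repolarization triangulation and Poincare
    beat-to-beat instability, detects early and delayed afterdepolarizations
    (EADs/DADs) and torsadogenic waveform irregularity, classifies tissues per
    dose as normal, arrhythmic, or weak/silent, aggregates dose-escalation
    cohorts with baseline normalization, Dunnett many-to-one comparisons and
    pairwise chi-squared incidence tests, and filters effluent biomarker panels
    by a limit of detection set three standard deviations above negative
    controls. Includes a fully parameterized synthetic-trace generator with
    known ground truth for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    minpack.lm,
    multcomp,
    mvtnorm,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
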