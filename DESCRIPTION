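Package: srmpanel
Title: Multiplexed SRM Quantification of Urinary Protein Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multiplexed selected reaction monitoring (SRM) assays
    of secreted protein biomarkers in urine. Computes peptide precursor and
    b/y fragment m/z values for light and stable-isotope-labelled heavy
    peptides, builds and validates transition tables, processes SRM
    chromatograms (peak detection, trapezoidal integration, signal-to-noise
    gating, matrix-interference flagging from transition intensity ratios),
    converts light/heavy peak-area ratios to amounts per 100 ug of total
    urinary protein with normalization against urinary PSA, and evaluates
    marker performance (exact Mann-Whitney rank tests, ROC curves with
    DeLong confidence intervals and Youden cutoffs, inter-peptide
    concordance, ridge-penalized logistic marker panels, risk
    stratification). Includes simulators for SRM chromatogram sets and
    clinical-style cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
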