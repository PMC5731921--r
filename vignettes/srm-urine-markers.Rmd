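---
title: "Quantifying urinary protein biomarkers by multiplexed SRM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying urinary protein biomarkers by multiplexed SRM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmpanel)
```

## The measurement problem

Selected reaction monitoring (SRM) on a triple-quadrupole instrument measures
a protein through one or more *surrogate peptides*: tryptic peptides unique to
the protein, each monitored as a small set of precursor-to-fragment
(Q1 to Q3) *transitions*. A stable-isotope-labelled copy of each surrogate
peptide (heavy on the C-terminal Lys or Arg: +8.014199 or +10.008269 Da) is
spiked into the digest at a known concentration, so that the ratio of light
(endogenous) to heavy (standard) peak areas — the **L/H ratio** — is directly
proportional to the amount of endogenous protein.

`srmpanel` implements this workflow for a multiplexed panel of
prostate-cancer-associated secreted proteins measured in voided urine, where
the clinically interesting analytes sit near the detection limit and the urine
matrix is aggressive: quantification has to defend itself with explicit QC
gates (retention-time agreement, signal-to-noise, matrix-interference checks)
before any statistics are computed.

## Transition arithmetic

All m/z computation uses monoisotopic residue masses, water 18.010565 Da and
a proton mass of 1.007276 Da. Carbamidomethylation (+57.02146 Da) is applied
to every cysteine as a fixed modification, reflecting iodoacetamide
alkylation during sample preparation; the packaged panel confirms this
convention, since every Cys-containing printed Q1 matches only with the shift
included.

```{r}
precursor_mz("LPQTLSR", 2)        # AGR2 surrogate, 2+
fragment_mz("AVIDDAFAR", "y", 7)  # MMP9 surrogate, y7 1+
```

Printed transition tables carry one decimal and omit charge states and
fragment identities. `annotate_panel()` reconstructs them: precursor charge is
chosen from {2, 3} by proximity to the printed Q1, and each printed Q3 is
assigned by an exhaustive search of the b/y series at fragment charge 1-2
within a +/-0.05 tolerance (half a printing unit). Ties prefer y over b and
the lower charge, because y ions at low charge dominate triple-quadrupole
transition selection in practice. A printed value that matches nothing within
tolerance is *reported as unassigned* rather than force-fitted; in the
packaged panel exactly one Q3 (579.4 for AVIDDAFAR, nearest y5 at 579.289)
falls in that category.

`screen_peptide()` applies the standard surrogate-selection criteria:
uniqueness as a tryptic substring of a reference proteome (cleavage after K/R,
suppressed before Pro), no oxidation-prone Met, and no annotated modification
sites. Any failure downgrades the verdict to a warning — such peptides can
still be measured, but their light signal may under-report the protein.

## Chromatogram processing

Each peptide in each sample contributes six traces (three transitions, light
and heavy). Processing follows the rules a human operator applies in a
Skyline-style review, made explicit:

* **Expected retention time** comes from the heavy standard: the spiked
  standard is always detectable, so its quantifier apex anchors the search
  window for the endogenous peptide.
* **Apex** is the maximum of the trace within +/-15 s
  (`search_half_window`) of the expected RT. The apex is *located* on a
  5-point running mean of the trace — locating it on the raw trace would jump
  onto single-point noise spikes on the peak flanks — but its intensity is
  read from the raw trace.
* **Boundaries** extend outward until the smoothed trace falls below 5% of
  the apex (`boundary_fraction`) or reaches a local minimum, capped at
  +/-30 s. A local minimum only counts as a boundary once the trace has
  dropped below half the apex: a genuine valley between co-eluting peaks sits
  low, while noise wiggles near the top of a peak do not.
* **Area** is the trapezoidal integral between the boundaries after
  subtracting a linear baseline through the boundary intensities, floored at
  zero. Light-channel areas are integrated over the *paired heavy
  transition's boundaries* — the usual convention for isotope-dilution data,
  which stops independent boundary noise in the weak light channel from
  biasing the ratio.
* **S/N** is the apex intensity over the highest background intensity within
  +/-15 s of the apex but outside the peak boundaries. This replaces the
  visual background inspection of interactive review with a deterministic
  rule. A zero or absent background is reported as the finite cap 1e6 rather
  than infinity so downstream arithmetic stays finite; anything at the cap is
  far above the quantifiability gate anyway.
* **Interference**: the heavy standard defines the expected relative
  intensity signature across the three transitions (normalized to sum 1).
  A light transition whose observed share deviates from its expected share by
  more than 20% relative (`interference_threshold`) is flagged; a flagged
  quantifier invalidates the peptide for that sample. The normalized dot
  product between the two signatures is carried as a secondary diagnostic.

A peptide in a sample is **detectable** when the light quantifier peak exists,
its apex agrees with the heavy apex within 6 s (`rt_tolerance`), its S/N is
at least 10 (`snr_min`), and its quantifier is not interference-flagged. A
cell that fails carries a reason code (`no_peak`, `rt_mismatch`, `low_snr`,
`interfered`) and is treated downstream as *missing, never zero*.

Thresholds and their defaults live in `srm_config()`. The S/N gate of 10 and
the +/-15 s background window are the workflow's defining constants; the RT
tolerance (6 s), boundary fraction (0.05), boundary cap (30 s), smoothing
width (5 points) and interference threshold (0.2) are this implementation's
conventions, surfaced in the config and echoed into every report so a run is
self-describing.

## From ratios to amounts, and PSA normalization

With heavy standards spiked at 10 fmol/uL into digest at 0.5 ug/uL (the
panel's conditions), an L/H of 1.0 corresponds to
`1.0 * 10 / 0.5 * 100 = 2000` fmol per 100 ug of total urinary protein;
`lh_to_amount()` also reports ng/100 ug when the protein's molecular weight
is supplied. Crude heavy standards are used uncorrected (a purity multiplier
exists, default 1).

Total-protein adjustment does not remove the dominant nuisance in urine: how
much *prostatic* secretion reached the sample. Urinary PSA serves as the
reference for that — `psa_origin_summary()` reproduces the justification, a
post-op/pre-op comparison in which prostatectomy collapses urinary PSA to
about 1% of its pre-op level, showing the prostate to be its essentially
exclusive source. `normalize_to_psa()` divides every marker's L/H by the
same sample's PSA-peptide L/H (reference column `IVGGWECEK`, cam-Cys
implied; the choice of the single reference peptide over an average of the
two PSA peptides follows the workflow's own normalization description).
Samples without a usable PSA value cannot be normalized and are dropped with
a logged reason. The headline post-op percentage is mean-based, with the
median-based figure reported alongside.

## Marker evaluation

* `rank_test()` is a two-sided Mann-Whitney U with midrank ties. For
  combined n up to 12 the null distribution is enumerated over all label
  assignments, so P values are exact even with ties (the two-sided P is the
  probability of a |U - E[U]| at least as large as observed); beyond that a
  tie-corrected normal approximation with continuity correction is used.
* `roc()` builds the curve over all distinct thresholds and integrates by
  trapezoid, which reproduces the tie-adjusted Mann-Whitney identity
  AUC = U/(n1 n2). The 95% CI uses the DeLong placement-value variance on
  the log-odds scale: the logit-transformed interval stays inside (0, 1) and
  holds nominal coverage clearly better at cohort-scale n (14 vs 6) than the
  linear-scale interval, which we measured at ~89% empirical coverage
  against ~97% for the logit form.
* Orientation is *fixed* by default (higher score = cancer). An
  auto-flipping mode exists and records the flip, but it is not the default:
  an anti-concordant marker should be allowed to report its AUC below 0.5
  honestly, and auto-flipping biases small-sample AUC estimates upward.
* `optimal_cutoff()` maximizes sensitivity + specificity (Youden). Ties
  break toward higher specificity — in a biopsy-sparing application a false
  positive costs an invasive procedure — then toward the higher threshold.
  A best achievable sum of 1 (e.g. constant scores) is flagged degenerate.
* `concordance()` correlates L/H ratios between surrogate peptides of the
  same protein on pairwise-complete samples; well-behaved surrogates of one
  protein should track each other, and a pair with r-squared below 0.5 is
  marked as a discordance candidate (the signature of an unknown
  modification on one peptide). Values are never imputed.
* `fit_panel()` combines markers by maximum-likelihood logistic regression
  with a small ridge penalty (lambda = 1e-4) on the slopes, which keeps
  coefficients finite under the perfect separation that is routine at n = 20.
  The panel score is the linear predictor — AUC-identical to the fitted
  probability, so the choice is cosmetic. With no member set given, an
  exhaustive search over subsets up to `k_max = 5` markers picks the panel
  with the best training AUC; with 16 candidate markers that is 6,884 fits,
  still fast at these n. Training-set AUC of a searched panel is optimistic
  at this scale and is reported as such, not asserted to beat its members.
* `stratify()` reuses the rank test within the cancer group, comparing
  clinically significant disease (anything beyond Gleason <= 6 *and* tumor
  volume <= 0.5 cc) against low-volume/low-grade disease, typically on
  PSA-normalized values, with urinary and serum PSA as comparators.
* Per-peptide P values are reported raw; a Benjamini-Hochberg column is
  appended as clearly-labelled supplementary output.

## What the simulators emulate — and what they do not

`simulate_chromatogram_set()` produces co-eluting Gaussian transition peaks:
heavy amplitudes follow a fixed signature (default 0.5/0.3/0.2), the light
channel is the heavy shape scaled by the true L/H, and additive Gaussian
noise, optional point spikes, an optional light-channel RT shift and an
optional co-eluting contaminant in one transition complete the picture.
Defaults — apex at 300 s, peak sigma 4 s, 1 s sampling, heavy apex 1e4
counts — give peaks of realistic width and sampling density for a scheduled
SRM run. Every generator is a pure function of its configuration including
the seed.

`simulate_cohort()` draws log-normal L/H values (ratios are positive and
right-skewed; medians are the natural location summary) for a cohort of 14
cancer, 6 non-cancer and 7 post-op donors — the sizes of the study design
this pipeline targets, with the cancer group split 6 low-grade vs 5
significant plus 3 without histology. The generative model is, per sample i
and peptide j of protein p:

    log LH_ij = baseline + delta_p * cancer_i + log(fold_p) * significant_i
                + s_i + sd_pep * (sqrt(rho) * c_pi + sqrt(1 - rho) * e_ij)

with `s_i` a per-sample *prostatic secretion factor* (sd 1) shared by every
marker **and by PSA** — this shared factor is exactly what makes raw L/H
values weak classifiers and what PSA normalization cancels; PSA itself has no
group effect. `c_pi` is protein-level noise shared by that protein's
peptides, giving within-protein peptide correlation `rho` (default 0.7, the
median concordance the workflow reports for real urine). Effect sizes are
parameterized by a target *normalized* AUC per protein (default 0.85, the
middle of the 0.75-0.87 range the panel achieves after normalization) through
the binormal identity `delta = 2 * qnorm(target_auc) * sd_pep`. MMP9 carries
an additional 12-fold shift in clinically significant cancer, mirroring its
transcript-level behavior. Post-op PSA is scaled to 1% of pre-op by
construction.

Not emulated: raw spectra and isotope envelopes, retention-time drift across
runs, heteroscedastic detector noise, batch effects, or the long right tail
of benign-hyperplasia PSA. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and well calibrated under a faithful
statistical cartoon of the study — they are not evidence about any particular
clinical cohort.

## Problem sizes used by the test suite

The suite enumerates the rank-test null exactly up to n1 + n2 = 8 against an
independent pair-counting oracle; checks AUC identities on 50 random small
datasets; recovers binormal AUCs of 0.6/0.75/0.87 at n = 14/6 over 500
replicates each (mean within 0.05); measures L/H recovery on 100 simulated
chromatogram sets across the ratio grid 0.01-10 (median relative error under
10%); measures interference recall on 200 contaminated sets (+50% on one
transition, recall at least 95%); and verifies on 200 replicate cohorts that
PSA normalization raises the AUC of a secretion-confounded marker. These
sizes keep the full suite under a minute on one core while leaving the Monte
Carlo margins comfortable.

## Known limitations

* Peak detection assumes a single chromatographic peak per trace inside the
  search window; it picks the nearest/tallest candidate rather than
  deconvolving overlaps.
* DeLong intervals collapse to a point at sample AUCs of exactly 0 or 1;
  coverage at n = 14/6 is good but not exact.
* The exhaustive panel search reports training-set performance; no internal
  cross-validation is attempted at n = 20.
* Absolute molar concentrations per urine volume are out of scope (per-sample
  urine volumes are not part of the data model); amounts are reported per
  100 ug of total urinary protein.
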