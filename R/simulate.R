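# Synthetic data with known ground truth: (1) SRM chromatogram sets —
# co-eluting Gaussian transition peaks with a fixed intensity-ratio signature,
# additive noise, optional spikes and co-eluting interference; (2) cohort
# marker matrices — log-normal L/H abundances with per-protein effect sizes,
# within-protein peptide correlation, a per-sample prostatic secretion factor
# shared with PSA, and a post-op PSA channel at a fixed fraction of pre-op.

#' Configuration for one simulated chromatogram set
#'
#' @param true_lh True light/heavy ratio (ground truth for recovery tests).
#' @param signature Relative intensity signature of the three transitions
#'   (normalized internally to sum 1).
#' @param apex_rt Peak apex retention time, s.
#' @param peak_sigma Gaussian peak width (sd), s.
#' @param sampling_interval Chromatogram sampling step, s.
#' @param half_window Trace half-width around `apex_rt`, s.
#' @param heavy_apex Apex intensity (counts) of the strongest heavy
#'   transition.
#' @param noise_sd Additive Gaussian noise sd (counts); intensities are
#'   floored at 0.
#' @param spike_prob Per-point probability of an extra noise spike.
#' @param spike_height Spike intensity (counts).
#' @param light_rt_shift Shift of the light peak apex relative to heavy, s
#'   (nonzero values emulate a wrong-peak pick).
#' @param interference Optional co-eluting contaminant in one light
#'   transition: list with `transition` (index 1-3), `rel_height` (relative
#'   to that transition's light apex) and `rt_offset` (s).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `chrom_sim_config`.
#' @export
chrom_sim_config <- function(true_lh = 1, signature = c(0.5, 0.3, 0.2),
                             apex_rt = 300, peak_sigma = 4,
                             sampling_interval = 1, half_window = 60,
                             heavy_apex = 1e4, noise_sd = 20,
                             spike_prob = 0, spike_height = 0,
                             light_rt_shift = 0, interference = NULL,
                             seed = 1L) {
  if (true_lh < 0) stop("true_lh must be >= 0")
  if (length(signature) != 3L || any(signature <= 0)) {
    stop("signature must be 3 positive values")
  }
  for (v in list(peak_sigma = peak_sigma,
                 sampling_interval = sampling_interval,
                 half_window = half_window, heavy_apex = heavy_apex)) {
    if (v <= 0) stop("peak_sigma, sampling_interval, half_window, heavy_apex must be positive")
  }
  if (noise_sd < 0 || spike_prob < 0 || spike_prob > 1) {
    stop("noise_sd >= 0 and spike_prob in [0, 1] required")
  }
  if (!is.null(interference)) {
    stopifnot(is.list(interference),
              interference$transition %in% 1:3,
              interference$rel_height >= 0)
    if (is.null(interference$rt_offset)) interference$rt_offset <- 0
  }
  structure(list(true_lh = true_lh, signature = signature / sum(signature),
                 apex_rt = apex_rt, peak_sigma = peak_sigma,
                 sampling_interval = sampling_interval,
                 half_window = half_window, heavy_apex = heavy_apex,
                 noise_sd = noise_sd, spike_prob = spike_prob,
                 spike_height = spike_height,
                 light_rt_shift = light_rt_shift,
                 interference = interference, seed = as.integer(seed)),
            class = "chrom_sim_config")
}

#' Simulate one SRM chromatogram set
#'
#' Generates light and heavy traces for three transitions of one peptide in
#' one sample. Heavy traces are Gaussian peaks whose amplitudes follow the
#' configured signature; light traces are the heavy shape scaled by
#' `true_lh` (shifted by `light_rt_shift` if set), with additive Gaussian
#' noise, optional point spikes and optional co-eluting interference added to
#' one light transition. Deterministic for a fixed config.
#'
#' @param cfg A [chrom_sim_config()].
#' @param sample_id,peptide Identifiers stamped on the rows.
#' @param fragments Three transition labels (default `c("t1","t2","t3")`;
#'   use the assay table's fragment labels to feed [quantify_group()]).
#' @return A list: `chromatograms` (long-format data.frame as accepted by
#'   [quantify_group()]) and `truth` (the config's ground-truth values).
#' @export
simulate_chromatogram_set <- function(cfg, sample_id = "S1",
                                      peptide = "PEPTIDEK",
                                      fragments = c("t1", "t2", "t3")) {
  stopifnot(inherits(cfg, "chrom_sim_config"), length(fragments) == 3L)
  set.seed(cfg$seed)
  tt <- seq(cfg$apex_rt - cfg$half_window, cfg$apex_rt + cfg$half_window,
            by = cfg$sampling_interval)
  amp <- cfg$heavy_apex * cfg$signature / max(cfg$signature)
  gauss <- function(center, a) a * exp(-(tt - center)^2 / (2 * cfg$peak_sigma^2))

  rows <- list()
  for (i in 1:3) {
    for (lab in c("heavy", "light")) {
      y <- if (lab == "heavy") gauss(cfg$apex_rt, amp[i])
           else gauss(cfg$apex_rt + cfg$light_rt_shift, amp[i] * cfg$true_lh)
      if (lab == "light" && !is.null(cfg$interference) &&
          cfg$interference$transition == i) {
        y <- y + gauss(cfg$apex_rt + cfg$interference$rt_offset,
                       amp[i] * cfg$true_lh * cfg$interference$rel_height)
      }
      if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(tt), 0, cfg$noise_sd)
      if (cfg$spike_prob > 0) {
        y <- y + cfg$spike_height *
          (stats::runif(length(tt)) < cfg$spike_prob)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, peptide = peptide, fragment = fragments[i],
        fragment_charge = 1L, label = lab, time_sec = tt,
        intensity = pmax(y, 0), stringsAsFactors = FALSE)
    }
  }
  list(
    chromatograms = do.call(rbind, rows),
    truth = list(true_lh = cfg$true_lh, signature = cfg$signature,
                 apex_rt = cfg$apex_rt,
                 interference = cfg$interference)
  )
}

#' Simulate a chromatogram batch for a marker matrix
#'
#' Turns each (sample, peptide) cell of a marker matrix into a simulated
#' chromatogram set whose true L/H equals the cell value, keyed by the assay
#' table's fragment labels so the batch feeds straight into [run_quant()].
#' Missing cells emit heavy traces with a noise-only light channel.
#'
#' @param m A `marker_matrix` of true L/H values.
#' @param assay An `assay_table` covering the matrix's peptides.
#' @param seed Integer master seed; each set draws a sub-seed from it.
#' @param ... Overrides passed to every cell's [chrom_sim_config()].
#' @return A long-format chromatogram data.frame.
#' @export
simulate_chromatogram_batch <- function(m, assay, seed = 1L, ...) {
  peptides <- intersect(colnames(m), unique(assay$peptide))
  if (!length(peptides)) stop("assay table covers none of the matrix peptides")
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max,
                         length(peptides) * nrow(m))
  out <- vector("list", length(peptides) * nrow(m))
  k <- 0L
  for (pep in peptides) {
    frags <- assay$fragment[assay$peptide == pep]
    for (s in rownames(m)) {
      k <- k + 1L
      lh <- m[s, pep]
      cfg <- chrom_sim_config(true_lh = if (is.finite(lh)) lh else 0,
                              seed = subseeds[k], ...)
      out[[k]] <- simulate_chromatogram_set(cfg, sample_id = s, peptide = pep,
                                            fragments = frags)$chromatograms
    }
  }
  do.call(rbind, out)
}

#' Configuration for a simulated clinical cohort
#'
#' The cohort layout mirrors the study conditions the pipeline is meant for:
#' 14 cancer (pre-op), 6 non-cancer and 7 post-op urine donors, with the
#' cancer group split 6 low-volume/low-grade vs 5 clinically significant
#' (plus 3 without histology). Marker abundances are log-normal; each
#' protein's effect size is derived from a target (PSA-normalized) binormal
#' AUC; all prostate-derived channels — markers and PSA alike — share a
#' per-sample secretion factor, which confounds raw L/H values and is what
#' PSA normalization removes. Post-op PSA is scaled to a fixed fraction of
#' pre-op, emulating prostate removal.
#'
#' @param n_cancer,n_noncancer,n_postop Group sizes (defaults 14 / 6 / 7).
#' @param markers data.frame with columns `peptide`, `protein` and optionally
#'   `target_auc`; default: the printed transition panel's 16 cohort-testable
#'   peptides plus the two PSA peptides.
#' @param target_auc Default per-protein normalized AUC (0.85) used where the
#'   markers table does not override it; PSA is always null (AUC 0.5).
#' @param rho Within-protein correlation of the peptide noise component.
#' @param peptide_sd Log-scale sd of per-peptide noise.
#' @param secretion_sd Log-scale sd of the shared per-sample prostatic
#'   secretion factor.
#' @param baseline_log,psa_baseline_log Log-scale baselines of marker and PSA
#'   L/H.
#' @param postop_psa_fraction Post-op PSA as a fraction of pre-op
#'   (default 0.01).
#' @param sig_fold Named per-protein fold-change between clinically
#'   significant and low-grade cancer (default `c(MMP9 = 12)`).
#' @param n_low_grade,n_significant Cancer-strata sizes (defaults 6 / 5; the
#'   remainder lack histology).
#' @param missing_rate Probability a cell is missing (reason `no_peak`).
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_cancer = 14, n_noncancer = 6, n_postop = 7,
                              markers = NULL, target_auc = 0.85, rho = 0.7,
                              peptide_sd = 0.5, secretion_sd = 1,
                              baseline_log = 0, psa_baseline_log = 1,
                              postop_psa_fraction = 0.01,
                              sig_fold = c(MMP9 = 12),
                              n_low_grade = 6, n_significant = 5,
                              missing_rate = 0.02, seed = 1L) {
  if (any(c(n_cancer, n_noncancer, n_postop) < 0)) stop("group sizes must be >= 0")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (peptide_sd <= 0 || secretion_sd < 0) {
    stop("peptide_sd > 0 and secretion_sd >= 0 required")
  }
  if (postop_psa_fraction <= 0 || postop_psa_fraction > 1) {
    stop("postop_psa_fraction must be in (0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_low_grade + n_significant > n_cancer) {
    stop("strata sizes exceed the cancer group")
  }
  if (is.null(markers)) markers <- default_cohort_markers()
  if (is.null(markers$target_auc)) markers$target_auc <- target_auc
  markers$target_auc[markers$protein == "PSA"] <- 0.5
  if (any(markers$target_auc < 0.5 | markers$target_auc >= 1)) {
    stop("target_auc must be in [0.5, 1)")
  }
  structure(list(n_cancer = n_cancer, n_noncancer = n_noncancer,
                 n_postop = n_postop, markers = markers, rho = rho,
                 peptide_sd = peptide_sd, secretion_sd = secretion_sd,
                 baseline_log = baseline_log,
                 psa_baseline_log = psa_baseline_log,
                 postop_psa_fraction = postop_psa_fraction,
                 sig_fold = sig_fold, n_low_grade = n_low_grade,
                 n_significant = n_significant,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

default_cohort_markers <- function() {
  panel <- prostate_panel()
  # peptides quantifiable across the cohort (drops CCL3 and POSTN single
  # peptides and the three panel peptides not carried into cohort testing)
  keep <- c("LPQTLSR", "LYTYEPR", "SDLVNEEATGQFR", "EVLLLAHNLPQNR",
            "WANQCNYR", "YEDLYSNCK", "MVIITTK", "LWEAFWAVK", "AVIDDAFAR",
            "FQTFEGDLK", "LGLGADVAQVTGALR", "SLGPALLLLQK",
            "GVCISPEAIVTDLPEDVK", "VLYLSAFTSK", "VTSLTACLVDQSLR",
            "HVLFGTVGVPEHTYR")
  mk <- panel[panel$peptide %in% keep, c("peptide", "protein")]
  rbind(mk,
        data.frame(peptide = c("IVGGWECEK", "LSEPAELTDAVK"),
                   protein = "PSA", stringsAsFactors = FALSE))
}

#' Simulate a cohort marker matrix with ground truth
#'
#' Draws the log-normal model described in [cohort_sim_config()]: for sample
#' *i* and peptide *j* of protein *p*,
#' `log LH_ij = baseline + delta_p * cancer_i + log(sig_fold_p) * significant_i
#'  + s_i + sd_pep * (sqrt(rho) * c_pi + sqrt(1-rho) * e_ij)`,
#' where `s_i` is the shared secretion factor and `c_pi` the protein-level
#' noise shared by that protein's peptides. The effect size `delta_p` is set
#' from the protein's target normalized AUC:
#' `delta = 2 * qnorm(target_auc) * peptide_sd` (binormal identity with the
#' PSA reference contributing an equal, independent noise term). Post-op
#' samples have no cancer effect and PSA multiplied by
#' `postop_psa_fraction`.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list: `matrix` (a `marker_matrix` of L/H values), `manifest`
#'   (see [read_manifest()]), `truth` (per-protein `delta`, expected raw and
#'   normalized AUC, per-sample secretion factors).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  ids <- c(sprintf("S%02dN", seq_len(cfg$n_noncancer)),
           sprintf("S%02dC", cfg$n_noncancer + seq_len(cfg$n_cancer)),
           sprintf("POST%02d", seq_len(cfg$n_postop)))
  group <- rep(c("non-cancer", "cancer", "post-op"),
               c(cfg$n_noncancer, cfg$n_cancer, cfg$n_postop))
  n <- length(ids)

  gleason <- rep(NA_real_, n)
  volume <- rep(NA_real_, n)
  ci <- which(group == "cancer")
  if (cfg$n_low_grade > 0) {
    sel <- ci[seq_len(cfg$n_low_grade)]
    gleason[sel] <- sample(5:6, length(sel), replace = TRUE)
    volume[sel] <- stats::runif(length(sel), 0.1, 0.5)
  }
  if (cfg$n_significant > 0) {
    sel <- ci[cfg$n_low_grade + seq_len(cfg$n_significant)]
    gleason[sel] <- sample(7:9, length(sel), replace = TRUE)
    volume[sel] <- stats::runif(length(sel), 0.6, 3)
  }
  serum_psa <- ifelse(group == "post-op", NA_real_,
                      stats::rlnorm(n, meanlog = ifelse(group == "cancer",
                                                        log(6), log(2)),
                                    sdlog = 0.5))
  manifest <- read_manifest(data.frame(
    sample_id = ids, group = group,
    total_protein = round(stats::runif(n, 200, 300), 1),
    gleason = gleason, tumor_volume_cc = volume,
    serum_psa = round(serum_psa, 2), stringsAsFactors = FALSE))

  mk <- cfg$markers
  proteins <- unique(mk$protein)
  delta <- stats::setNames(2 * stats::qnorm(mk$target_auc[match(proteins,
                                                                mk$protein)]) *
                             cfg$peptide_sd, proteins)
  s_i <- stats::rnorm(n, 0, cfg$secretion_sd)
  is_cancer <- as.numeric(group == "cancer")
  is_sig <- as.numeric(manifest$significance == "significant")

  m <- matrix(NA_real_, n, nrow(mk), dimnames = list(ids, mk$peptide))
  cfac <- matrix(stats::rnorm(n * length(proteins)), n,
                 dimnames = list(NULL, proteins))
  for (j in seq_len(nrow(mk))) {
    prot <- mk$protein[j]
    base <- if (prot == "PSA") cfg$psa_baseline_log else cfg$baseline_log
    eff <- if (prot == "PSA") 0 else delta[[prot]] * is_cancer
    strat <- if (prot %in% names(cfg$sig_fold)) {
      log(cfg$sig_fold[[prot]]) * is_sig
    } else 0
    noise <- cfg$peptide_sd * (sqrt(cfg$rho) * cfac[, prot] +
                                 sqrt(1 - cfg$rho) * stats::rnorm(n))
    lv <- base + eff + strat + s_i + noise
    if (prot == "PSA") {
      lv <- lv + log(cfg$postop_psa_fraction) * (group == "post-op")
    }
    m[, j] <- exp(lv)
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(m)) < cfg$missing_rate, nrow(m))
    drop[, mk$protein == "PSA"] <- FALSE  # reference channel kept complete
    m[drop] <- NA_real_
  }
  na_idx <- which(is.na(m), arr.ind = TRUE)
  reasons <- data.frame(sample_id = rownames(m)[na_idx[, 1]],
                        peptide = colnames(m)[na_idx[, 2]],
                        reason = rep("no_peak", nrow(na_idx)),
                        stringsAsFactors = FALSE)
  attr(m, "reasons") <- reasons
  class(m) <- c("marker_matrix", class(m))

  truth <- list(
    delta = delta,
    expected_auc_normalized = stats::pnorm(delta / (sqrt(2) *
                                                      sqrt(2 * cfg$peptide_sd^2))),
    expected_auc_raw = stats::pnorm(delta / (sqrt(2) *
                                               sqrt(cfg$peptide_sd^2 +
                                                      cfg$secretion_sd^2))),
    secretion = stats::setNames(s_i, ids),
    config = cfg
  )
  list(matrix = m, manifest = manifest, truth = truth)
}
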