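# Conversion of L/H peak-area ratios to amounts per 100 ug of total urinary
# protein, normalization against urinary PSA as a reference of
# prostate-specific secretion, and the pre-op vs post-op PSA comparison.

#' Convert an L/H ratio to an amount per 100 ug of total urinary protein
#'
#' With heavy standards spiked at a fixed molar concentration into a digest of
#' fixed peptide concentration, the endogenous amount per ug of digested
#' protein is `lh * spike_conc / digest_conc`; reporting per 100 ug multiplies
#' by 100. When the protein's molecular weight is supplied the mass amount in
#' ng/100 ug is returned alongside.
#'
#' @param lh L/H peak-area ratio (vectorized), >= 0.
#' @param spike_conc Heavy-standard spike concentration in fmol/uL
#'   (default 10, the panel's spike level).
#' @param digest_conc Digest peptide concentration in ug/uL (default 0.5).
#' @param protein_mw Optional protein molecular weight in Da (g/mol).
#' @param purity Heavy-standard purity multiplier (default 1; crude standards
#'   are used uncorrected, a pure-standard correction can be supplied here).
#' @return A data.frame with columns `lh`, `fmol_per_100ug` and (when
#'   `protein_mw` is given) `ng_per_100ug`.
#' @examples
#' lh_to_amount(1.0)                       # 2000 fmol/100 ug
#' lh_to_amount(1.0, protein_mw = 28700)   # adds 57.4 ng/100 ug
#' @export
lh_to_amount <- function(lh, spike_conc = 10, digest_conc = 0.5,
                         protein_mw = NULL, purity = 1) {
  if (any(!is.finite(lh)) || any(lh < 0)) stop("lh must be finite and >= 0")
  for (v in list(spike_conc = spike_conc, digest_conc = digest_conc,
                 purity = purity)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop("spike_conc, digest_conc and purity must be positive scalars")
    }
  }
  fmol <- lh * purity * spike_conc / digest_conc * 100
  out <- data.frame(lh = lh, fmol_per_100ug = fmol)
  if (!is.null(protein_mw)) {
    if (!is.numeric(protein_mw) || protein_mw <= 0) {
      stop("protein_mw must be a positive scalar (Da)")
    }
    out$ng_per_100ug <- fmol * protein_mw * 1e-6
  }
  out
}

#' Invert an amount per 100 ug back to the implied L/H ratio
#'
#' @param fmol_per_100ug Amount in fmol per 100 ug of total protein.
#' @inheritParams lh_to_amount
#' @return The implied L/H ratio.
#' @export
amount_to_lh <- function(fmol_per_100ug, spike_conc = 10, digest_conc = 0.5,
                         purity = 1) {
  fmol_per_100ug / 100 * digest_conc / (purity * spike_conc)
}

#' Normalize a marker matrix against urinary PSA
#'
#' Divides every marker L/H by the same sample's PSA-peptide L/H, using
#' urinary PSA as a reference of prostate-specific secretion. Samples whose
#' PSA value is missing or non-positive cannot be normalized and are dropped
#' with a logged reason; missing marker cells stay missing. The PSA column
#' itself maps to 1.
#'
#' @param m A `marker_matrix` (samples x peptides, L/H ratios).
#' @param psa_peptide Column used as reference (default `"IVGGWECEK"`,
#'   carbamidomethyl Cys implied).
#' @return A `marker_matrix` of normalized ratios, with dropped samples
#'   recorded in `attr(, "dropped")` (data.frame `sample_id`, `reason`).
#' @export
normalize_to_psa <- function(m, psa_peptide = "IVGGWECEK") {
  if (!psa_peptide %in% colnames(m)) {
    stop("PSA reference column '", psa_peptide, "' not present")
  }
  psa <- m[, psa_peptide]
  bad <- !is.finite(psa) | psa <= 0
  dropped <- data.frame(
    sample_id = rownames(m)[bad],
    reason = ifelse(is.finite(psa[bad]) & psa[bad] <= 0,
                    "nonpositive_psa", "missing_psa"),
    stringsAsFactors = FALSE
  )
  out <- m[!bad, , drop = FALSE] / psa[!bad]
  reasons <- attr(m, "reasons")
  if (!is.null(reasons)) {
    attr(out, "reasons") <-
      reasons[reasons$sample_id %in% rownames(out), , drop = FALSE]
  }
  attr(out, "dropped") <- dropped
  attr(out, "psa_peptide") <- psa_peptide
  class(out) <- c("marker_matrix", class(unclass(out)))
  out
}

#' Summarize pre-op vs post-op urinary PSA
#'
#' Compares PSA amounts in urine collected before and after radical
#' prostatectomy. A post-op level near zero relative to pre-op indicates that
#' urinary PSA originates from the prostate. The headline percentage is
#' mean-based (rounded to the nearest integer percent); the median-based
#' percentage is reported alongside.
#'
#' @param pre_op,post_op Numeric vectors of PSA amounts (same units, e.g.
#'   ng/100 ug of total urinary protein).
#' @return An object of class `psa_origin`: means, medians,
#'   `pct_mean` (100 * mean(post)/mean(pre)), `pct_mean_headline` (rounded),
#'   `pct_median`.
#' @examples
#' psa_origin_summary(pre_op = 110.89, post_op = 0.98)  # ~1%
#' @export
psa_origin_summary <- function(pre_op, post_op) {
  pre_op <- pre_op[is.finite(pre_op)]
  post_op <- post_op[is.finite(post_op)]
  if (!length(pre_op) || !length(post_op)) {
    stop("both pre-op and post-op groups must be non-empty")
  }
  structure(
    list(
      n_pre = length(pre_op), n_post = length(post_op),
      mean_pre = mean(pre_op), mean_post = mean(post_op),
      median_pre = stats::median(pre_op), median_post = stats::median(post_op),
      pct_mean = 100 * mean(post_op) / mean(pre_op),
      pct_mean_headline = round(100 * mean(post_op) / mean(pre_op)),
      pct_median = 100 * stats::median(post_op) / stats::median(pre_op)
    ),
    class = "psa_origin"
  )
}

#' @export
print.psa_origin <- function(x, ...) {
  cat("<psa_origin>\n")
  cat(sprintf("  pre-op  (n=%d): mean %.2f, median %.2f\n",
              x$n_pre, x$mean_pre, x$median_pre))
  cat(sprintf("  post-op (n=%d): mean %.2f, median %.2f\n",
              x$n_post, x$mean_post, x$median_post))
  cat(sprintf("  post-op as %% of pre-op: ~%d%% by means (%.2f%%), %.1f%% by medians\n",
              x$pct_mean_headline, x$pct_mean, x$pct_median))
  invisible(x)
}

#' Read a sample manifest
#'
#' Reads the cohort manifest CSV (`sample_id`, optional `group`,
#' `total_protein`, `gleason`, `tumor_volume_cc`, `serum_psa`). When `group`
#' is absent it is derived from the sample-code suffix convention: suffix `N`
#' denotes non-cancer, suffix `C` cancer (pre-op); anything else is treated as
#' post-op. A `significance` column is derived for cancer samples:
#' `low_grade` when Gleason <= 6 and tumor volume <= 0.5 cc, `significant`
#' when both fields are present and the low-grade criteria fail, `n.a.`
#' otherwise.
#'
#' @param path Manifest CSV path, or a data.frame already in memory.
#' @return A data.frame with the columns above, `group` as a factor with
#'   levels `non-cancer`, `cancer`, `post-op`.
#' @export
read_manifest <- function(path) {
  x <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(x)) stop("manifest lacks a sample_id column")
  if (anyDuplicated(x$sample_id)) stop("manifest has duplicate sample ids")
  if (is.null(x$group)) {
    suffix <- substr(x$sample_id, nchar(x$sample_id), nchar(x$sample_id))
    x$group <- ifelse(suffix == "N", "non-cancer",
                      ifelse(suffix == "C", "cancer", "post-op"))
  }
  bad <- !x$group %in% c("non-cancer", "cancer", "post-op")
  if (any(bad)) {
    stop("unknown group label(s): ", paste(unique(x$group[bad]), collapse = ", "))
  }
  x$group <- factor(x$group, levels = c("non-cancer", "cancer", "post-op"))
  for (col in c("total_protein", "gleason", "tumor_volume_cc", "serum_psa")) {
    if (is.null(x[[col]])) x[[col]] <- NA_real_
  }
  x$significance <- derive_significance(x)
  x
}

derive_significance <- function(x) {
  out <- rep("n.a.", nrow(x))
  cc <- x$group == "cancer" & is.finite(x$gleason) &
    is.finite(x$tumor_volume_cc)
  out[cc & x$gleason <= 6 & x$tumor_volume_cc <= 0.5] <- "low_grade"
  out[cc & !(x$gleason <= 6 & x$tumor_volume_cc <= 0.5)] <- "significant"
  out
}
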