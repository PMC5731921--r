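# End-to-end orchestration: chromatogram batch -> marker matrix + QC report,
# and marker matrix + manifest -> performance / concordance / panel /
# stratification report.

#' Quantify a chromatogram batch into a marker matrix
#'
#' Applies [quantify_group()] to every (sample, peptide) pair present in a
#' long-format chromatogram batch and assembles the L/H marker matrix and a
#' per-pair QC table. Deterministic given its inputs.
#'
#' @param chrom Long-format chromatogram data.frame or CSV path
#'   (see [read_chromatograms()]).
#' @param assay An `assay_table` or assay CSV path.
#' @param config An [srm_config()].
#' @param output_dir Optional directory; when given, writes
#'   `marker_matrix.csv` (+ `_reasons.csv` sidecar) and `qc_report.csv`.
#' @return A list of class `quant_run`: `matrix` (a `marker_matrix`), `qc`
#'   (data.frame, one row per sample x peptide), `config`.
#' @export
run_quant <- function(chrom, assay, config = srm_config(),
                      output_dir = NULL) {
  if (is.character(chrom)) chrom <- read_chromatograms(chrom)
  else chrom <- validate_chromatograms(chrom)
  if (is.character(assay)) assay <- read_assay_table(assay)

  pairs <- unique(chrom[c("sample_id", "peptide")])
  quants <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    sub <- chrom[chrom$sample_id == pairs$sample_id[k] &
                   chrom$peptide == pairs$peptide[k], , drop = FALSE]
    quants[[k]] <- quantify_group(sub, assay, config)
  }
  qc <- do.call(rbind, lapply(quants, function(q) data.frame(
    sample_id = q$sample_id, peptide = q$peptide, quantifier = q$quantifier,
    rt_heavy = q$rt_heavy, rt_light = q$rt_light, rt_match = q$rt_match,
    snr = q$snr, interference_quantifier =
      unname(q$interference_flags[q$quantifier]),
    detectable = q$detectable, reason = q$reason, lh = q$lh,
    stringsAsFactors = FALSE)))
  out <- structure(list(matrix = marker_matrix(quants), qc = qc,
                        config = config),
                   class = "quant_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_marker_matrix(out$matrix, file.path(output_dir, "marker_matrix.csv"))
    utils::write.csv(qc, file.path(output_dir, "qc_report.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.quant_run <- function(x, ...) {
  cat(sprintf("<quant_run> %d samples x %d peptides; %d of %d cells detectable\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(is.finite(x$matrix)), length(x$matrix)))
  if (nrow(attr(x$matrix, "reasons"))) {
    print(table(attr(x$matrix, "reasons")$reason))
  }
  invisible(x)
}

#' Per-peptide marker performance table
#'
#' For each marker: two-sided rank-test P and ROC AUC on the raw L/H values
#' and on the PSA-normalized values, plus the Youden cutoff's sensitivity and
#' specificity on the normalized scale. A Benjamini-Hochberg adjusted column
#' (`p_norm_bh`) is appended as supplementary output; the per-peptide P values
#' themselves are unadjusted.
#'
#' @param m Raw `marker_matrix`.
#' @param manifest Manifest (see [read_manifest()]); only cancer vs
#'   non-cancer samples enter.
#' @param psa_peptide Reference column for normalization.
#' @param peptides Markers to evaluate (default: all non-PSA columns).
#' @return A data.frame of class `performance_table`.
#' @export
marker_performance <- function(m, manifest, psa_peptide = "IVGGWECEK",
                               peptides = NULL) {
  mn <- normalize_to_psa(m, psa_peptide)
  if (is.null(peptides)) {
    peptides <- setdiff(colnames(m), c(psa_peptide, "LSEPAELTDAVK"))
  }
  grp <- function(mm) {
    mf <- manifest[match(rownames(mm), manifest$sample_id), ]
    list(cancer = mf$group == "cancer", noncancer = mf$group == "non-cancer")
  }
  g_raw <- grp(m)
  g_nrm <- grp(mn)

  one <- function(pep) {
    vr <- m[, pep]
    vn <- mn[, pep]
    ca <- vr[g_raw$cancer & is.finite(vr)]
    nc <- vr[g_raw$noncancer & is.finite(vr)]
    can <- vn[g_nrm$cancer & is.finite(vn)]
    ncn <- vn[g_nrm$noncancer & is.finite(vn)]
    rt_raw <- rank_test(ca, nc)
    rt_nrm <- rank_test(can, ncn)
    roc_raw <- roc(c(ca, nc), rep(c(TRUE, FALSE), c(length(ca), length(nc))),
                   positive = TRUE)
    roc_nrm <- roc(c(can, ncn),
                   rep(c(TRUE, FALSE), c(length(can), length(ncn))),
                   positive = TRUE)
    cut <- optimal_cutoff(roc_nrm)
    data.frame(peptide = pep,
               n_cancer = length(can), n_noncancer = length(ncn),
               p_raw = rt_raw$p_value, auc_raw = roc_raw$auc,
               p_norm = rt_nrm$p_value, auc_norm = roc_nrm$auc,
               auc_norm_lo = roc_nrm$ci[1], auc_norm_hi = roc_nrm$ci[2],
               cutoff = cut$cutoff, sensitivity = cut$sensitivity,
               specificity = cut$specificity, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(peptides, one))
  out$p_norm_bh <- stats::p.adjust(out$p_norm, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Full downstream report for a quantified cohort
#'
#' Composes the downstream analyses on a marker matrix and its manifest:
#' per-peptide performance (raw and PSA-normalized), inter-peptide
#' concordance per protein, the best logistic panel (exhaustive subset search
#' on normalized, log-transformed markers), and — when the manifest carries
#' histology — risk stratification of the cancer group. All sections reuse
#' the module functions directly, so report numbers equal direct calls.
#'
#' @param m A `marker_matrix` (raw L/H).
#' @param manifest Manifest data.frame or CSV path.
#' @param protein_map Peptide-to-protein map (default: from the printed
#'   panel plus the PSA peptides).
#' @param psa_peptide Normalization reference (default `"IVGGWECEK"`).
#' @param k_max Largest panel size searched (default 5).
#' @param config An [srm_config()] echoed into the report.
#' @param output_dir Optional directory for the report CSVs.
#' @return A list of class `srm_report` with elements `performance`,
#'   `concordance`, `panel`, `stratification` (or `NA` when histology is
#'   absent), `psa_peptide`, `config`.
#' @export
run_report <- function(m, manifest, protein_map = NULL,
                       psa_peptide = "IVGGWECEK", k_max = 5,
                       config = srm_config(), output_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!all(rownames(m) %in% manifest$sample_id)) {
    stop("matrix and manifest sample ids do not agree")
  }
  if (is.null(protein_map)) {
    mk <- default_cohort_markers()
    protein_map <- stats::setNames(mk$protein, mk$peptide)
  }
  if (!psa_peptide %in% colnames(m)) {
    warning("no PSA column '", psa_peptide,
            "'; normalized sections skipped")
    perf <- NULL
    mn <- NULL
  } else {
    perf <- marker_performance(m, manifest, psa_peptide)
    mn <- normalize_to_psa(m, psa_peptide)
  }
  conc <- concordance(m, protein_map)

  panel <- NULL
  if (!is.null(mn)) {
    mf <- manifest[match(rownames(mn), manifest$sample_id), ]
    keep <- mf$group %in% c("cancer", "non-cancer")
    labels <- as.character(mf$group[keep])
    markers <- setdiff(colnames(mn), c(psa_peptide, "LSEPAELTDAVK"))
    panel <- fit_panel(mn[keep, markers, drop = FALSE], labels,
                       k_max = k_max)
  }

  strat <- NULL
  mf_all <- manifest[match(rownames(m), manifest$sample_id), ]
  has_strata <- !is.null(mn) &&
    length(unique(stats::na.omit(
      mf_all$significance[mf_all$significance != "n.a."]))) == 2
  if (has_strata) {
    upsa <- stats::setNames(m[, psa_peptide], rownames(m))
    strat <- stratify(mn, manifest,
                      peptides = setdiff(colnames(mn),
                                         c(psa_peptide, "LSEPAELTDAVK")),
                      upsa = upsa[rownames(mn)])
  }

  out <- structure(list(performance = perf, concordance = conc,
                        panel = panel, stratification = strat,
                        psa_peptide = psa_peptide, config = config),
                   class = "srm_report")
  if (!is.null(output_dir)) write_report(out, output_dir)
  out
}

#' @export
print.srm_report <- function(x, ...) {
  cat("<srm_report>\n")
  if (!is.null(x$performance)) {
    cat(sprintf("  performance: %d peptides, normalized AUC %.2f-%.2f\n",
                nrow(x$performance), min(x$performance$auc_norm),
                max(x$performance$auc_norm)))
  }
  if (!is.null(x$concordance) && nrow(x$concordance)) {
    r2 <- x$concordance$r_squared
    cat(sprintf("  concordance: %d pairs, r^2 %.2f-%.2f\n",
                nrow(x$concordance),
                suppressWarnings(min(r2, na.rm = TRUE)),
                suppressWarnings(max(r2, na.rm = TRUE))))
  }
  if (!is.null(x$panel)) {
    cat(sprintf("  best panel (%d members): AUC %.2f, P = %.3g\n",
                length(x$panel$members), x$panel$auc, x$panel$p_value))
  }
  if (!is.null(x$stratification)) {
    cat(sprintf("  stratification: %d comparisons, min P = %.3g\n",
                nrow(x$stratification), min(x$stratification$p_value,
                                            na.rm = TRUE)))
  } else {
    cat("  stratification: n.a.\n")
  }
  invisible(x)
}

#' Write a report's sections to CSV files
#'
#' @param report An `srm_report`.
#' @param output_dir Destination directory (created if absent).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(as.data.frame(df), file.path(output_dir, name),
                       row.names = FALSE)
    }
  }
  wr(report$performance, "performance.csv")
  wr(report$concordance, "concordance.csv")
  if (!is.null(report$panel)) {
    wr(data.frame(term = names(report$panel$coefficients),
                  estimate = unname(report$panel$coefficients)),
       "panel_coefficients.csv")
    wr(report$panel$search, "panel_search.csv")
  }
  wr(report$stratification, "stratification.csv")
  cfg <- report$config
  writeLines(c("# srmpanel report settings",
               sprintf("%s: %g", names(cfg), unlist(cfg)),
               sprintf("psa_peptide: %s", report$psa_peptide)),
             file.path(output_dir, "settings.txt"))
  invisible(output_dir)
}
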