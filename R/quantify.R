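# Light/heavy quantification of one peptide in one sample: fix the retention
# time from the heavy standard, detect light peaks in that window, gate on
# retention-time agreement, quantifier S/N and interference, and report the
# L/H peak-area ratio or a reason code.

#' Read / write long-format SRM chromatograms
#'
#' The on-disk format is a long CSV with one row per chromatogram point:
#' `sample_id`, `peptide`, `fragment`, `fragment_charge`, `label`
#' (`"light"`/`"heavy"`), `time_sec`, `intensity`. Times must be strictly
#' increasing within each (sample, peptide, fragment, label) trace.
#'
#' @param path File path.
#' @param x A chromatogram data.frame.
#' @return `read_chromatograms()` returns the validated data.frame;
#'   `write_chromatograms()` returns `path` invisibly.
#' @export
read_chromatograms <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_chromatograms(x, where = path)
}

#' @rdname read_chromatograms
#' @export
write_chromatograms <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

validate_chromatograms <- function(x, where = "chromatogram data") {
  need <- c("sample_id", "peptide", "fragment", "label", "time_sec",
            "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(where, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!nrow(x)) stop(where, " is empty")
  if (!all(x$label %in% c("light", "heavy"))) {
    bad <- which(!x$label %in% c("light", "heavy"))[1]
    stop(where, " row ", bad, ": label must be 'light' or 'heavy', got '",
         x$label[bad], "'")
  }
  if (any(!is.finite(x$time_sec)) || any(!is.finite(x$intensity))) {
    stop(where, ": non-finite time or intensity values")
  }
  key <- interaction(x$sample_id, x$peptide, x$fragment, x$label, drop = TRUE)
  bad <- vapply(split(x$time_sec, key), function(tt) any(diff(tt) <= 0),
                logical(1))
  if (any(bad)) {
    stop(where, ": non-monotone time in trace(s) ",
         paste(utils::head(names(bad)[bad], 3), collapse = "; "))
  }
  x
}

# re-aim a detected peak at externally supplied boundary times (mapped to the
# nearest grid points of this trace)
clamp_peak_to <- function(peak, time, left, right) {
  idx <- which(time >= left & time <= right)
  if (length(idx) < 2L) idx <- range(which.min(abs(time - left)),
                                     which.min(abs(time - right)))
  peak$left_index <- min(idx)
  peak$right_index <- max(idx)
  peak$left <- time[peak$left_index]
  peak$right <- time[peak$right_index]
  peak
}

#' Quantify one peptide in one sample from its light and heavy traces
#'
#' Runs the full per-peptide QC and quantification chain: detects the heavy
#' peaks (the expected retention time is taken from the heavy quantifier apex
#' unless supplied), derives the expected transition-ratio signature from the
#' heavy areas, detects light peaks in the same window (light areas are
#' integrated over the paired heavy transition's boundaries, as usual for
#' isotope-dilution data), and gates
#' detectability on (1) light/heavy apex agreement within `rt_tolerance`,
#' (2) quantifier S/N of at least `snr_min`, and (3) no interference flag on
#' the quantifier. The L/H ratio is the light over heavy quantifier area; when
#' not detectable the result carries a reason code (`no_peak`, `rt_mismatch`,
#' `low_snr`, `interfered`) so that downstream statistics can treat it as
#' missing rather than zero.
#'
#' @param chrom Long-format chromatogram data.frame (see
#'   [read_chromatograms()]) restricted to one sample and one peptide.
#' @param assay An `assay_table` (rows for this peptide are selected).
#' @param config An [srm_config()].
#' @param expected_rt Optional expected retention time (s); default is the
#'   global intensity maximum of the heavy quantifier trace.
#' @return An object of class `group_qc`: sample/peptide ids, heavy and light
#'   apex times, `rt_match`, `expected_ratios`, `observed_ratios`,
#'   `interference_flags`, `snr`, `detectable`, `reason`, per-transition
#'   areas, and `lh`.
#' @export
quantify_group <- function(chrom, assay, config = srm_config(),
                           expected_rt = NULL) {
  peptide <- unique(chrom$peptide)
  if (length(peptide) != 1L) {
    stop("quantify_group expects chromatograms of a single peptide, got ",
         length(peptide))
  }
  sample_id <- unique(chrom$sample_id)
  if (length(sample_id) != 1L) {
    stop("quantify_group expects chromatograms of a single sample, got ",
         length(sample_id))
  }
  arows <- assay[assay$peptide == peptide, , drop = FALSE]
  if (nrow(arows) != 3L) {
    stop("assay table carries ", nrow(arows), " transitions for ", peptide,
         "; need 3")
  }
  fragments <- arows$fragment
  quant <- which(arows$is_quantifier)

  trace <- function(frag, label) {
    tr <- chrom[chrom$fragment == frag & chrom$label == label, , drop = FALSE]
    if (!nrow(tr)) return(NULL)
    tr[order(tr$time_sec), c("time_sec", "intensity")]
  }

  heavy <- lapply(fragments, trace, label = "heavy")
  names(heavy) <- fragments
  absent <- fragments[vapply(heavy, is.null, logical(1))]
  if (length(absent)) {
    stop("heavy-standard trace missing for transition(s) ",
         paste(absent, collapse = ", "), " of ", peptide)
  }

  if (is.null(expected_rt)) {
    hq <- heavy[[quant]]
    expected_rt <- hq$time_sec[which.max(hq$intensity)]
  }

  heavy_peaks <- lapply(heavy, function(tr)
    detect_peak(tr$time_sec, tr$intensity, expected_rt, config))
  lost <- fragments[!vapply(heavy_peaks, `[[`, logical(1), "found")]
  if (length(lost)) {
    stop("heavy-standard peak not found for transition(s) ",
         paste(lost, collapse = ", "), " of ", peptide)
  }
  heavy_areas <- vapply(fragments, function(f)
    integrate_area(heavy[[f]]$time_sec, heavy[[f]]$intensity,
                   heavy_peaks[[f]]), numeric(1))
  expected <- expected_transition_ratios(heavy_areas)
  rt_heavy <- heavy_peaks[[quant]]$apex_time

  # light apexes are located independently (for the RT gate and S/N), but
  # integration reuses the heavy standard's boundaries per transition, the
  # usual paired-integration convention for isotope-dilution data
  light <- lapply(fragments, trace, label = "light")
  names(light) <- fragments
  light_peaks <- vector("list", length(fragments))
  names(light_peaks) <- fragments
  light_areas <- stats::setNames(rep(0, length(fragments)), fragments)
  for (f in fragments) {
    if (is.null(light[[f]])) next
    pk <- detect_peak(light[[f]]$time_sec, light[[f]]$intensity, rt_heavy,
                      config)
    light_peaks[[f]] <- pk
    if (pk$found) {
      paired <- clamp_peak_to(pk, light[[f]]$time_sec,
                              heavy_peaks[[f]]$left, heavy_peaks[[f]]$right)
      light_areas[[f]] <- integrate_area(light[[f]]$time_sec,
                                         light[[f]]$intensity, paired)
    }
  }

  res <- list(
    sample_id = sample_id, peptide = peptide,
    quantifier = fragments[quant], rt_heavy = rt_heavy,
    rt_light = NA_real_, rt_match = FALSE,
    expected_ratios = expected,
    observed_ratios = stats::setNames(rep(NA_real_, length(fragments)),
                                      fragments),
    interference_flags = stats::setNames(rep(NA, length(fragments)),
                                         fragments),
    snr = NA_real_, noise_level = NA_real_,
    heavy_areas = heavy_areas, light_areas = light_areas,
    detectable = FALSE, reason = NA_character_, lh = NA_real_
  )
  class(res) <- "group_qc"

  lq <- light_peaks[[quant]]
  if (is.null(lq) || !lq$found) {
    res$reason <- "no_peak"
    return(res)
  }
  res$rt_light <- lq$apex_time
  res$rt_match <- abs(lq$apex_time - rt_heavy) <= config$rt_tolerance
  sn <- signal_to_noise(light[[fragments[quant]]]$time_sec,
                        light[[fragments[quant]]]$intensity, lq, config)
  res$snr <- sn$snr
  res$noise_level <- sn$noise_level
  if (sum(light_areas) > 0) {
    res$observed_ratios <- light_areas / sum(light_areas)
    fi <- flag_interference(res$observed_ratios, expected,
                            config$interference_threshold)
    res$interference_flags <- fi$flags
    res$ratio_dot_product <- fi$dot_product
  }

  if (!res$rt_match) {
    res$reason <- "rt_mismatch"
  } else if (res$snr < config$snr_min) {
    res$reason <- "low_snr"
  } else if (isTRUE(res$interference_flags[[quant]])) {
    res$reason <- "interfered"
  } else {
    res$detectable <- TRUE
    res$lh <- light_areas[[quant]] / heavy_areas[[quant]]
  }
  res
}

#' @export
print.group_qc <- function(x, ...) {
  cat(sprintf("<group_qc> %s / %s (quantifier %s)\n",
              x$sample_id, x$peptide, x$quantifier))
  if (x$detectable) {
    cat(sprintf("  detectable: L/H = %.4g (S/N %.3g, apex %.1f s)\n",
                x$lh, x$snr, x$rt_light))
  } else {
    cat(sprintf("  not detectable (%s)\n", x$reason))
  }
  invisible(x)
}

#' Assemble a marker matrix from per-group quantification results
#'
#' @param quants A list of `group_qc` objects.
#' @return A numeric matrix (samples x peptides) of L/H ratios of class
#'   `marker_matrix`; cells that were not detectable are `NA` and their reason
#'   codes are kept in `attr(, "reasons")` (data.frame `sample_id`, `peptide`,
#'   `reason`).
#' @export
marker_matrix <- function(quants) {
  if (!length(quants)) stop("no quantification results supplied")
  samples <- unique(vapply(quants, `[[`, character(1), "sample_id"))
  peptides <- unique(vapply(quants, `[[`, character(1), "peptide"))
  m <- matrix(NA_real_, length(samples), length(peptides),
              dimnames = list(samples, peptides))
  reasons <- data.frame(sample_id = character(), peptide = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (q in quants) {
    if (q$detectable) {
      m[q$sample_id, q$peptide] <- q$lh
    } else {
      reasons <- rbind(reasons, data.frame(
        sample_id = q$sample_id, peptide = q$peptide, reason = q$reason,
        stringsAsFactors = FALSE))
    }
  }
  attr(m, "reasons") <- reasons
  class(m) <- c("marker_matrix", class(m))
  m
}

#' Read / write a marker matrix (wide CSV plus missing-reason sidecar)
#'
#' @param path CSV path for the wide samples x peptides matrix; reasons are
#'   read/written from `<path>` with suffix `_reasons.csv`.
#' @param x A `marker_matrix`.
#' @return `read_marker_matrix()` returns a `marker_matrix`;
#'   `write_marker_matrix()` returns `path` invisibly.
#' @export
read_marker_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  rpath <- sub("\\.csv$", "_reasons.csv", path)
  reasons <- if (file.exists(rpath)) {
    utils::read.csv(rpath, stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(), peptide = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  attr(m, "reasons") <- reasons
  class(m) <- c("marker_matrix", class(m))
  m
}

#' @rdname read_marker_matrix
#' @export
write_marker_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  reasons <- attr(x, "reasons")
  if (!is.null(reasons) && nrow(reasons)) {
    utils::write.csv(reasons, sub("\\.csv$", "_reasons.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
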