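# Multi-marker panels by ridge-penalized logistic regression (the small
# penalty keeps the fit finite under perfect separation at cohort sizes of
# ~20), and risk stratification of the cancer group.

# Ridge-penalized logistic IRLS; intercept unpenalized. Returns coefficients,
# linear predictor, convergence flag.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 200, tol = 1e-10) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  p <- ncol(x)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- tryCatch(
      solve(xtw %*% x + pen, xtw %*% z),
      error = function(e) stop("panel fit failed: singular system (",
                               conditionMessage(e), ")")
    )
    beta <- drop(beta_new)
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12))) +
      lambda * sum(beta[-1]^2)
    if (abs(dev - dev_old) < tol) { converged <- TRUE; break }
    dev_old <- dev
  }
  list(coefficients = stats::setNames(beta, colnames(x)),
       linear_predictor = drop(x %*% beta), converged = converged)
}

#' Fit a multi-marker panel by ridge-penalized logistic regression
#'
#' Combines a subset of surrogate-peptide markers into a single score via a
#' maximum-likelihood logistic fit with a small ridge penalty on the slopes
#' (default lambda = 1e-4), which keeps coefficients finite when the classes
#' separate perfectly at small n. The panel score is the linear predictor
#' (AUC-identical to the fitted probability); the panel is summarized by its
#' training-set ROC AUC and a rank-test P on the scores. With `members = NULL`
#' an exhaustive search over all subsets of up to `k_max` markers picks the
#' panel with the highest training AUC (ties to the smaller panel).
#'
#' Markers are log-transformed before fitting when `log_input = TRUE`
#' (default), matching the right-skew of L/H ratios.
#'
#' @param m A `marker_matrix` (raw or PSA-normalized).
#' @param labels Class labels aligned with `rownames(m)` (see [roc()]).
#' @param members Character vector of marker columns; `NULL` searches.
#' @param positive Positive-class label (default `"cancer"`).
#' @param lambda Ridge penalty (default 1e-4).
#' @param k_max Largest panel size searched when `members = NULL` (default 5).
#' @param log_input Log-transform marker values before fitting (default TRUE;
#'   zeros are lifted to half the smallest positive value).
#' @return An object of class `panel_model`: `members`, `coefficients`,
#'   `scores` (named linear predictor), `auc`, `auc_ci`, `p_value`,
#'   `n_dropped` (rows lost to missing members), `separation` (TRUE when the
#'   panel score separates the classes completely on the training data),
#'   `converged`,
#'   `search` (data.frame of searched panels, when a search ran).
#' @export
fit_panel <- function(m, labels, members = NULL, positive = "cancer",
                      lambda = 1e-4, k_max = 5, log_input = TRUE) {
  pos <- coerce_labels(labels, positive)
  x <- as.matrix(unclass(m))
  if (log_input) {
    minpos <- suppressWarnings(min(x[is.finite(x) & x > 0]))
    if (!is.finite(minpos)) stop("no positive marker values to log-transform")
    x[is.finite(x) & x <= 0] <- minpos / 2
    x <- log(x)
  }

  fit_one <- function(cols) {
    ok <- rowSums(!is.finite(x[, cols, drop = FALSE])) == 0 & !is.na(pos)
    xm <- x[ok, cols, drop = FALSE]
    y <- as.numeric(pos[ok])
    if (sum(y) < 2 || sum(1 - y) < 2) {
      stop("need at least 2 samples per class after dropping missing rows")
    }
    fit <- ridge_logistic(xm, y, lambda = lambda)
    r <- roc(fit$linear_predictor, y == 1, positive = TRUE)
    list(fit = fit, roc = r, ok = ok, y = y)
  }

  search_tab <- NULL
  if (is.null(members)) {
    cand <- colnames(x)
    rows <- list()
    best <- NULL
    for (k in seq_len(min(k_max, length(cand)))) {
      combos <- utils::combn(cand, k, simplify = FALSE)
      for (cc in combos) {
        f <- tryCatch(fit_one(cc), error = function(e) NULL)
        if (is.null(f)) next
        rows[[length(rows) + 1L]] <- data.frame(
          members = paste(cc, collapse = "+"), size = k, auc = f$roc$auc,
          stringsAsFactors = FALSE)
        if (is.null(best) || f$roc$auc > best$roc$auc + 1e-12) {
          best <- f
          members <- cc
        }
      }
    }
    if (is.null(best)) stop("panel search found no fittable subset")
    search_tab <- do.call(rbind, rows)
    search_tab <- search_tab[order(-search_tab$auc, search_tab$size), ]
    f <- best
  } else {
    miss <- setdiff(members, colnames(x))
    if (length(miss)) stop("unknown marker(s): ", paste(miss, collapse = ", "))
    f <- fit_one(members)
  }

  scores <- stats::setNames(f$fit$linear_predictor, rownames(x)[f$ok])
  pt <- rank_test(scores[f$y == 1], scores[f$y == 0])
  structure(
    list(members = members, coefficients = f$fit$coefficients,
         scores = scores, auc = f$roc$auc, auc_ci = f$roc$ci,
         p_value = pt$p_value, lambda = lambda,
         n_dropped = sum(!f$ok), separation = f$roc$auc == 1,
         converged = f$fit$converged, search = search_tab),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %d member(s): %s\n", length(x$members),
              paste(x$members, collapse = ", ")))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f), rank-test P = %.4g\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$p_value))
  if (x$separation) cat("  note: near-separation; coefficients penalty-bounded\n")
  if (x$n_dropped) cat(sprintf("  %d sample(s) dropped for missing members\n",
                               x$n_dropped))
  invisible(x)
}

#' Risk stratification of the cancer group
#'
#' Within cancer samples, compares clinically significant disease against
#' low-volume/low-grade disease (Gleason <= 6 and tumor volume <= 0.5 cc)
#' with a rank test per marker, typically on PSA-normalized values. Urinary
#' and serum PSA comparators can be supplied alongside.
#'
#' @param m A `marker_matrix` (rows must cover the cancer samples).
#' @param manifest A manifest from [read_manifest()] carrying `significance`.
#' @param peptides Marker columns to test (default: all columns of `m`).
#' @param upsa Optional named vector of urinary PSA values per sample (the
#'   un-normalized reference channel).
#' @return A data.frame of class `stratification_report`: `marker`, `n_low`,
#'   `n_significant`, `U`, `p_value`, `median_low`, `median_significant`.
#' @export
stratify <- function(m, manifest, peptides = colnames(m), upsa = NULL) {
  mf <- manifest[match(rownames(m), manifest$sample_id), , drop = FALSE]
  low <- rownames(m)[mf$group == "cancer" & mf$significance == "low_grade"]
  sig <- rownames(m)[mf$group == "cancer" & mf$significance == "significant"]
  low <- low[!is.na(low)]
  sig <- sig[!is.na(sig)]
  if (!length(low) || !length(sig)) {
    stop("both strata (low_grade, significant) must be non-empty")
  }

  one <- function(name, values) {
    a <- values[sig]
    b <- values[low]
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    if (!length(a) || !length(b)) {
      return(data.frame(marker = name, n_low = length(b),
                        n_significant = length(a), U = NA_real_,
                        p_value = NA_real_, median_low = NA_real_,
                        median_significant = NA_real_,
                        stringsAsFactors = FALSE))
    }
    rt <- rank_test(a, b)
    data.frame(marker = name, n_low = length(b), n_significant = length(a),
               U = rt$U, p_value = rt$p_value,
               median_low = stats::median(b),
               median_significant = stats::median(a),
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(peptides, function(p)
    one(p, stats::setNames(m[, p], rownames(m)))))
  if (!is.null(upsa)) out <- rbind(out, one("urinary_PSA", upsa))
  if (any(is.finite(mf$serum_psa))) {
    out <- rbind(out, one("serum_PSA",
                          stats::setNames(mf$serum_psa, mf$sample_id)))
  }
  rownames(out) <- NULL
  class(out) <- c("stratification_report", "data.frame")
  out
}
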