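# Transition-table construction and validation. An assay row is one
# protein/peptide/transition with light and heavy Q1/Q3; each peptide carries
# exactly three transitions, one of them the designated quantifier.

#' Printed transition panel for the urinary prostate-cancer markers
#'
#' The multiplexed panel of prostate-cancer-associated secreted proteins and
#' their surrogate tryptic peptides, as printed in a transition table: one row
#' per peptide with the precursor Q1 and three fragment Q3 values (one decimal).
#' Used as the reference against which the m/z machinery is validated, and as a
#' realistic default panel for simulations.
#'
#' @return A data.frame with columns `protein`, `accession`, `peptide`, `q1`,
#'   `q3_1`, `q3_2`, `q3_3`.
#' @examples
#' head(prostate_panel())
#' @export
prostate_panel <- function() {
  path <- system.file("extdata", "prostate_panel.csv", package = "srmpanel",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Annotate a printed transition panel
#'
#' For each panel row, recomputes the precursor m/z at charges 2 and 3, keeps
#' the charge closest to the printed Q1, and assigns every printed Q3 to a b/y
#' fragment with [annotate_q3()]. Q3 values with no fragment within tolerance
#' are kept and reported with `assigned = FALSE` rather than dropped.
#'
#' @param panel A data.frame in the layout of [prostate_panel()].
#' @param tol Matching tolerance in Da/charge (default 0.05; tables print one
#'   decimal).
#' @param charges Candidate precursor charges (default `c(2, 3)`).
#' @return A data.frame, one row per (peptide, transition): `protein`,
#'   `accession`, `peptide`, `precursor_charge`, `q1_printed`, `q1_calc`,
#'   `q1_delta`, `transition_rank`, `q3_printed`, `fragment`, `fragment_charge`,
#'   `q3_calc`, `q3_delta`, `assigned`.
#' @export
annotate_panel <- function(panel = prostate_panel(), tol = 0.05,
                           charges = c(2, 3)) {
  q3_cols <- grep("^q3_", names(panel), value = TRUE)
  out <- lapply(seq_len(nrow(panel)), function(k) {
    row <- panel[k, ]
    p <- peptide_spec(row$peptide, protein = row$protein,
                      accession = row$accession)
    mzs <- vapply(charges, function(z) precursor_mz(p, z), numeric(1))
    zi <- which.min(abs(mzs - row$q1))
    rows <- lapply(seq_along(q3_cols), function(j) {
      ann <- annotate_q3(p, row[[q3_cols[j]]], tol = tol)
      data.frame(
        protein = row$protein, accession = row$accession,
        peptide = row$peptide, precursor_charge = charges[zi],
        q1_printed = row$q1, q1_calc = mzs[zi],
        q1_delta = abs(mzs[zi] - row$q1),
        transition_rank = j, q3_printed = row[[q3_cols[j]]],
        fragment = if (ann$assigned) paste0(ann$series, ann$index)
                   else NA_character_,
        fragment_charge = ann$charge, q3_calc = ann$mz, q3_delta = ann$delta,
        assigned = ann$assigned, stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

parse_fragment <- function(fragment) {
  ok <- grepl("^[by][0-9]+$", fragment)
  if (!all(ok)) {
    stop("malformed fragment label(s): ",
         paste(unique(fragment[!ok]), collapse = ", "),
         " (expected e.g. 'y7')")
  }
  list(series = substr(fragment, 1, 1),
       index = as.integer(sub("^[by]", "", fragment)))
}

#' Build a light/heavy transition assay table
#'
#' Takes declared transition choices — three fragments per peptide, exactly one
#' flagged as the quantifier — and computes light and heavy Q1/Q3 for each.
#' The heavy standard shares the sequence with a 13C/15N label on the
#' C-terminal K/R, so heavy Q1 exceeds light Q1 by the label shift over the
#' charge, and y ions (which retain the C-terminus) shift while b ions do not.
#'
#' @param transitions A data.frame with one row per transition: columns
#'   `peptide`, `fragment` (e.g. `"y7"`), `is_quantifier` (logical), and
#'   optionally `protein`, `accession`, `precursor_charge` (default 2) and
#'   `fragment_charge` (default 1).
#' @return A data.frame of class `assay_table`, one row per transition:
#'   `protein`, `accession`, `peptide`, `fixed_mods`, `precursor_charge`,
#'   `fragment`, `fragment_charge`, `q1_light`, `q3_light`, `q1_heavy`,
#'   `q3_heavy`, `is_quantifier`.
#' @examples
#' tr <- data.frame(peptide = "AVIDDAFAR", fragment = c("y7", "y6", "y5"),
#'                  is_quantifier = c(TRUE, FALSE, FALSE))
#' build_assay_table(tr)
#' @export
build_assay_table <- function(transitions) {
  if (!nrow(transitions)) return(empty_assay_table())
  need <- c("peptide", "fragment", "is_quantifier")
  miss <- setdiff(need, names(transitions))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tr <- transitions
  if (is.null(tr$protein)) tr$protein <- NA_character_
  if (is.null(tr$accession)) tr$accession <- NA_character_
  if (is.null(tr$precursor_charge)) tr$precursor_charge <- 2L
  if (is.null(tr$fragment_charge)) tr$fragment_charge <- 1L

  dup <- duplicated(tr[c("peptide", "fragment", "fragment_charge")])
  if (any(dup)) {
    stop("duplicate (peptide, fragment) row(s): ",
         paste(unique(paste(tr$peptide[dup], tr$fragment[dup])), collapse = ", "))
  }
  out <- lapply(split(tr, tr$peptide), function(g) {
    if (nrow(g) != 3L) {
      stop("peptide ", g$peptide[1], " declares ", nrow(g),
           " transitions; exactly 3 are required")
    }
    if (sum(g$is_quantifier) != 1L) {
      stop("peptide ", g$peptide[1],
           " must flag exactly one quantifier transition")
    }
    light <- peptide_spec(g$peptide[1], protein = g$protein[1],
                          accession = g$accession[1])
    heavy <- peptide_spec(g$peptide[1], heavy = TRUE)
    fr <- parse_fragment(g$fragment)
    z <- g$precursor_charge[1]
    data.frame(
      protein = g$protein, accession = g$accession, peptide = g$peptide,
      fixed_mods = if (grepl("C", g$peptide[1])) "cam-C" else "",
      precursor_charge = z, fragment = g$fragment,
      fragment_charge = g$fragment_charge,
      q1_light = precursor_mz(light, z),
      q3_light = mapply(function(s, i, fz) fragment_mz(light, s, i, fz),
                        fr$series, fr$index, g$fragment_charge),
      q1_heavy = precursor_mz(heavy, z),
      q3_heavy = mapply(function(s, i, fz) fragment_mz(heavy, s, i, fz),
                        fr$series, fr$index, g$fragment_charge),
      is_quantifier = g$is_quantifier, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("assay_table", "data.frame")
  out
}

empty_assay_table <- function() {
  out <- data.frame(
    protein = character(), accession = character(), peptide = character(),
    fixed_mods = character(), precursor_charge = integer(),
    fragment = character(), fragment_charge = integer(),
    q1_light = numeric(), q3_light = numeric(), q1_heavy = numeric(),
    q3_heavy = numeric(), is_quantifier = logical(), stringsAsFactors = FALSE
  )
  class(out) <- c("assay_table", "data.frame")
  out
}

#' Pick quantifier-grade y-ion transitions for a peptide
#'
#' Deterministic transition designer for peptides without a printed table
#' entry: ranks singly charged y ions by index (largest first), keeps those in
#' a triple-quadrupole-friendly m/z range, and returns the top `n` with the
#' first flagged as quantifier.
#'
#' @param peptide Sequence string.
#' @param n Number of transitions (default 3).
#' @param mz_range Acceptable Q3 window (default `c(300, 1250)`).
#' @param precursor_charge Assumed precursor charge (default 2).
#' @return A transition data.frame suitable for [build_assay_table()].
#' @examples
#' design_transitions("IVGGWECEK")
#' @export
design_transitions <- function(peptide, n = 3, mz_range = c(300, 1250),
                               precursor_charge = 2L) {
  p <- peptide_spec(peptide)
  len <- nchar(peptide)
  idx <- rev(seq_len(len - 1))
  mz <- vapply(idx, function(i) fragment_mz(p, "y", i), numeric(1))
  keep <- idx[mz >= mz_range[1] & mz <= mz_range[2]]
  if (length(keep) < n) {
    stop("only ", length(keep), " y ions of ", peptide, " fall in [",
         mz_range[1], ", ", mz_range[2], "]; need ", n)
  }
  keep <- keep[seq_len(n)]
  data.frame(
    peptide = peptide, fragment = paste0("y", keep), fragment_charge = 1L,
    precursor_charge = precursor_charge,
    is_quantifier = seq_len(n) == 1L, stringsAsFactors = FALSE
  )
}

#' Read / write an assay table CSV
#'
#' The on-disk format is the one-row-per-transition CSV produced by
#' [build_assay_table()]; `read_assay_table()` re-validates the three-transition
#' and single-quantifier invariants on the way in.
#'
#' @param path File path.
#' @param x An `assay_table`.
#' @return `read_assay_table()` returns an `assay_table`;
#'   `write_assay_table()` returns `path` invisibly.
#' @export
read_assay_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peptide", "fragment", "fragment_charge", "precursor_charge",
            "q1_light", "q3_light", "q1_heavy", "q3_heavy", "is_quantifier")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("assay CSV ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  x$is_quantifier <- as.logical(x$is_quantifier)
  for (g in split(x, x$peptide)) {
    if (nrow(g) != 3L || sum(g$is_quantifier) != 1L) {
      stop("assay CSV invariant violated for peptide ", g$peptide[1],
           ": need 3 transitions and exactly 1 quantifier")
    }
  }
  class(x) <- c("assay_table", "data.frame")
  x
}

#' @rdname read_assay_table
#' @export
write_assay_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
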