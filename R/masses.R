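# Monoisotopic mass arithmetic for tryptic peptides and their SRM transitions.
# Conventions: carbamidomethyl is a fixed modification on every Cys (iodoacetamide
# alkylation); heavy internal standards carry 13C/15N on the C-terminal K or R.

#' Physical constants used in m/z arithmetic
#'
#' Monoisotopic residue masses for the 20 canonical amino acids plus the
#' constants used throughout: proton mass, water mass, the carbamidomethyl-Cys
#' shift and the 13C/15N heavy-label shifts on C-terminal Lys and Arg.
#'
#' @return A named list with elements `residues` (named numeric vector of
#'   residue masses, Da), `proton`, `water`, `cam`, `heavy_k`, `heavy_r`.
#' @examples
#' srm_constants()$residues[["G"]]
#' @export
srm_constants <- function() {
  list(
    residues = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
      T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
      N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
      E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
      R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    proton  = 1.007276,
    water   = 18.010565,
    cam     = 57.02146,
    heavy_k = 8.014199,
    heavy_r = 10.008269
  )
}

#' Construct a peptide specification
#'
#' A `peptide_spec` couples a peptide sequence with its fixed modifications and
#' isotope-label state. Carbamidomethylation of cysteine is applied as a fixed
#' modification by default, matching iodoacetamide alkylation during sample
#' preparation. A heavy peptide carries the isotope label on its C-terminal
#' residue, which must be K or R (tryptic C-terminus).
#'
#' @param sequence Uppercase amino-acid string (20 canonical residues).
#' @param heavy Logical; `TRUE` for the stable-isotope-labelled standard.
#' @param cam_cys Logical; apply +57.02146 Da to every Cys (default `TRUE`).
#' @param protein,accession Optional annotations carried along.
#' @return An object of class `peptide_spec`.
#' @examples
#' peptide_spec("LPQTLSR")
#' peptide_spec("AVIDDAFAR", heavy = TRUE)
#' @export
peptide_spec <- function(sequence, heavy = FALSE, cam_cys = TRUE,
                         protein = NA_character_, accession = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("peptide sequence must be non-empty")
  const <- srm_constants()
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(const$residues))
  if (length(bad)) {
    stop("non-canonical residue(s) in '", sequence, "': ",
         paste(unique(bad), collapse = ", "))
  }
  if (isTRUE(heavy) && !res[length(res)] %in% c("K", "R")) {
    stop("heavy label requires a C-terminal K or R, got '",
         res[length(res)], "' in ", sequence)
  }
  structure(
    list(sequence = sequence, heavy = isTRUE(heavy), cam_cys = isTRUE(cam_cys),
         protein = protein, accession = accession),
    class = "peptide_spec"
  )
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("<peptide_spec> %s%s%s  M = %.4f Da\n",
              x$sequence,
              if (x$heavy) " [heavy]" else "",
              if (x$cam_cys && grepl("C", x$sequence)) " [cam-C]" else "",
              peptide_neutral_mass(x)))
  invisible(x)
}

as_peptide_spec <- function(p, ...) {
  if (inherits(p, "peptide_spec")) p else peptide_spec(p, ...)
}

# Per-residue masses with fixed mods and (for heavy peptides) the label shift
# folded onto the residue carrying it. Internal workhorse for all m/z math.
residue_mass_vector <- function(p) {
  const <- srm_constants()
  res <- strsplit(p$sequence, "")[[1]]
  m <- const$residues[res]
  if (p$cam_cys) m[res == "C"] <- m[res == "C"] + const$cam
  if (p$heavy) {
    cterm <- length(res)
    m[cterm] <- m[cterm] +
      if (res[cterm] == "K") const$heavy_k else const$heavy_r
  }
  unname(m)
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus fixed-modification
#' shifts and, for heavy peptides, the isotope-label shift.
#'
#' @param p A `peptide_spec` or a plain sequence string (coerced with defaults).
#' @param ... Passed to [peptide_spec()] when `p` is a string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass("G")        # 75.03203
#' peptide_neutral_mass("LPQTLSR")  # 813.4708
#' @export
peptide_neutral_mass <- function(p, ...) {
  p <- as_peptide_spec(p, ...)
  sum(residue_mass_vector(p)) + srm_constants()$water
}

#' Precursor m/z of a protonated peptide
#'
#' @param p A `peptide_spec` or sequence string.
#' @param z Precursor charge, integer >= 1.
#' @param ... Passed to [peptide_spec()] when `p` is a string.
#' @return `(neutral mass + z * 1.007276) / z`.
#' @examples
#' precursor_mz("LPQTLSR", 2)    # 407.74
#' precursor_mz("AVIDDAFAR", 2)  # 489.26
#' @export
precursor_mz <- function(p, z = 2, ...) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z)) {
    stop("charge z must be a single integer >= 1")
  }
  const <- srm_constants()
  (peptide_neutral_mass(p, ...) + z * const$proton) / z
}

#' Fragment ion m/z (b and y series)
#'
#' y_n is the C-terminal fragment of n residues (keeps the water and, for heavy
#' peptides, the label); b_n is the N-terminal fragment of n residues.
#'
#' @param p A `peptide_spec` or sequence string.
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, `1 <= index <= nchar(sequence) - 1`.
#' @param z Fragment charge, integer >= 1.
#' @param ... Passed to [peptide_spec()] when `p` is a string.
#' @return Fragment m/z in Da/charge.
#' @examples
#' fragment_mz("AVIDDAFAR", "y", 7)       # 807.41
#' fragment_mz("LPQTLSR", "y", 6, z = 2)  # 351.20
#' @export
fragment_mz <- function(p, series = c("y", "b"), index, z = 1, ...) {
  series <- match.arg(series)
  p <- as_peptide_spec(p, ...)
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z)) {
    stop("charge z must be a single integer >= 1")
  }
  n <- nchar(p$sequence)
  if (!is.numeric(index) || length(index) != 1L || index != round(index) ||
      index < 1 || index > n - 1) {
    stop("fragment index must be in 1..", n - 1, " for ", p$sequence)
  }
  const <- srm_constants()
  m <- residue_mass_vector(p)
  if (series == "y") {
    (sum(m[(n - index + 1):n]) + const$water + z * const$proton) / z
  } else {
    (sum(m[1:index]) + z * const$proton) / z
  }
}

#' Assign a printed Q3 value to a fragment ion
#'
#' Searches the b and y series of the light peptide at fragment charges 1 and 2
#' for the ion nearest to a printed Q3 value. Ties within numerical noise are
#' broken by preferring y over b, then the lower charge. Transition tables are
#' customarily printed to one decimal, hence the default +/-0.05 tolerance.
#'
#' @param p A `peptide_spec` or sequence string (light).
#' @param q3 Printed Q3 value (m/z).
#' @param tol Assignment tolerance in Da/charge (default 0.05).
#' @param max_charge Highest fragment charge searched (default 2).
#' @return A one-row data.frame with columns `series`, `index`, `charge`, `mz`,
#'   `delta`, `assigned`. When no ion falls within `tol`, `assigned` is `FALSE`
#'   and `series`/`index`/`charge` are `NA` (a valid, reportable outcome).
#' @examples
#' annotate_q3("LPQTLSR", 604.3)  # y5, 1+
#' annotate_q3("LPQTLSR", 351.2)  # y6, 2+
#' @export
annotate_q3 <- function(p, q3, tol = 0.05, max_charge = 2) {
  p <- as_peptide_spec(p)
  p$heavy <- FALSE
  n <- nchar(p$sequence)
  cand <- expand.grid(series = c("y", "b"), index = seq_len(n - 1),
                      charge = seq_len(max_charge),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand$mz <- mapply(function(s, i, z) fragment_mz(p, s, i, z),
                    cand$series, cand$index, cand$charge)
  cand$delta <- abs(cand$mz - q3)
  # stable preference: y before b, then lower charge, for ties in |delta|
  cand <- cand[order(cand$delta, cand$series != "y", cand$charge), ]
  best <- cand[1L, ]
  if (best$delta <= tol) {
    data.frame(series = best$series, index = best$index, charge = best$charge,
               mz = best$mz, delta = best$delta, assigned = TRUE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(series = NA_character_, index = NA_integer_,
               charge = NA_integer_, mz = best$mz, delta = best$delta,
               assigned = FALSE, stringsAsFactors = FALSE)
  }
}
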