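# Surrogate-peptide screening: sequence uniqueness against a proteome and
# modification-risk flags. A good surrogate is unique to its protein, free of
# oxidation-prone residues and of annotated modification sites.

#' Screen a surrogate peptide for quantification suitability
#'
#' Checks the criteria a surrogate peptide must meet to stand in for its
#' protein: (a) the sequence occurs exactly once in the proteome as a tryptic
#' peptide, (b) no oxidation-prone Met residues, (c) no annotated modification
#' sites (e.g. phosphosites) inside the sequence. Any failed check downgrades
#' the verdict to `"warn"`; the peptide may still be usable but its light
#' signal can under-report the protein.
#'
#' Tryptic occurrence means the match is preceded by K/R (or the protein
#' N-terminus) and ends in K/R (or at the protein C-terminus), with cleavage
#' suppressed before proline.
#'
#' @param peptide Sequence string or `peptide_spec`.
#' @param proteome Optional: path to a FASTA file, or a named character vector
#'   of protein sequences. When absent, uniqueness is reported as `NA`.
#' @param mod_sites Optional data.frame of annotated modification sites with
#'   columns `peptide`, `position` (1-based within the peptide) and `type`.
#' @return An object of class `screen_report`: list with `peptide`,
#'   `unique_in_fasta` (TRUE/FALSE/NA), `n_occurrences`, `modification_flags`
#'   (data.frame `position`, `concern`), `verdict` (`"pass"`/`"warn"`).
#' @examples
#' screen_peptide("LPQTLSR")
#' @export
screen_peptide <- function(peptide, proteome = NULL, mod_sites = NULL) {
  p <- as_peptide_spec(peptide)
  seqs <- NULL
  if (!is.null(proteome)) {
    looks_like_path <- is.character(proteome) && length(proteome) == 1L &&
      (file.exists(proteome) || grepl("[/\\\\.]", proteome))
    if (looks_like_path) {
      if (!file.exists(proteome)) {
        stop("unreadable FASTA '", proteome, "': no such file")
      }
      fa <- tryCatch(
        seqinr::read.fasta(proteome, seqtype = "AA", as.string = TRUE),
        error = function(e) stop("unreadable FASTA '", proteome, "': ",
                                 conditionMessage(e))
      )
      seqs <- toupper(vapply(fa, function(s) as.character(s)[1], character(1)))
    } else if (is.character(proteome)) {
      seqs <- toupper(proteome)
    } else {
      stop("proteome must be a FASTA path or a character vector of sequences")
    }
  }

  n_occ <- NA_integer_
  unique_in_fasta <- NA
  if (!is.null(seqs)) {
    n_occ <- sum(vapply(seqs, count_tryptic_occurrences,
                        integer(1), peptide = p$sequence))
    unique_in_fasta <- n_occ == 1L
  }

  flags <- data.frame(position = integer(), concern = character(),
                      stringsAsFactors = FALSE)
  met <- which(strsplit(p$sequence, "")[[1]] == "M")
  if (length(met)) {
    flags <- rbind(flags, data.frame(position = met,
                                     concern = "Met-oxidation",
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(mod_sites) && nrow(mod_sites)) {
    hits <- mod_sites[mod_sites$peptide == p$sequence, , drop = FALSE]
    if (nrow(hits)) {
      flags <- rbind(flags, data.frame(position = as.integer(hits$position),
                                       concern = as.character(hits$type),
                                       stringsAsFactors = FALSE))
    }
  }

  verdict <- if (nrow(flags) > 0 || isFALSE(unique_in_fasta)) "warn" else "pass"
  structure(
    list(peptide = p$sequence, unique_in_fasta = unique_in_fasta,
         n_occurrences = n_occ, modification_flags = flags, verdict = verdict),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %s: %s\n", x$peptide, toupper(x$verdict)))
  cat(sprintf("  unique in proteome: %s",
              if (is.na(x$unique_in_fasta)) "not checked"
              else as.character(x$unique_in_fasta)))
  if (!is.na(x$n_occurrences)) cat(sprintf(" (%d tryptic occurrence(s))",
                                           x$n_occurrences))
  cat("\n")
  if (nrow(x$modification_flags)) {
    for (k in seq_len(nrow(x$modification_flags))) {
      cat(sprintf("  flag: %s at position %d\n",
                  x$modification_flags$concern[k],
                  x$modification_flags$position[k]))
    }
  }
  invisible(x)
}

# Count occurrences of `peptide` in `protein` with tryptic boundaries:
# preceded by K/R (not before P) or protein start; ends in K/R (with the next
# residue not P) or at the protein end.
count_tryptic_occurrences <- function(protein, peptide) {
  hits <- gregexpr(peptide, protein, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  len <- nchar(peptide)
  np <- nchar(protein)
  ok <- vapply(hits, function(i) {
    nterm_ok <- i == 1L ||
      (substr(protein, i - 1L, i - 1L) %in% c("K", "R") &&
         substr(peptide, 1L, 1L) != "P")
    end <- i + len - 1L
    cterm_ok <- (end == np && TRUE) ||
      (substr(peptide, len, len) %in% c("K", "R") &&
         (end == np || substr(protein, end + 1L, end + 1L) != "P"))
    nterm_ok && cterm_ok
  }, logical(1))
  sum(ok)
}
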