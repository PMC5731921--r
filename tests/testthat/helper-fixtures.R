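# Fixtures built in code: simple traces, a minimal assay, and a convenience
# wrapper that simulates one chromatogram set keyed to that assay.

gaussian_trace <- function(center = 30, amp = 1000, sigma = 2,
                           times = seq(0, 60, 0.5), baseline = 0) {
  list(time = times,
       intensity = baseline + amp * exp(-(times - center)^2 / (2 * sigma^2)))
}

# assay with three y transitions of a toy peptide; first is the quantifier
toy_assay <- function(peptide = "PEPTIDEK") {
  build_assay_table(data.frame(
    peptide = peptide, fragment = c("y6", "y5", "y4"),
    is_quantifier = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE))
}

sim_set <- function(..., peptide = "PEPTIDEK") {
  cfg <- chrom_sim_config(...)
  simulate_chromatogram_set(cfg, sample_id = "S1", peptide = peptide,
                            fragments = c("y6", "y5", "y4"))
}

# independent Mann-Whitney oracle: U by direct pair counting, exact two-sided
# P by enumerating all label assignments of the pooled values
oracle_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

oracle_rank_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  u_obs <- oracle_u(a, b)
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    oracle_u(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force AUC: probability a random positive outranks a random negative
oracle_auc <- function(scores, pos) {
  x1 <- scores[pos]
  x0 <- scores[!pos]
  mean(outer(x1, x0, ">") + 0.5 * outer(x1, x0, "=="))
}
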