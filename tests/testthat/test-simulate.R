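# Simulator properties: replay determinism, programmed correlation and effect
# sizes recovered, post-op PSA fraction by construction.

test_that("chromatogram sets replay identically under a fixed seed", {
  a <- sim_set(true_lh = 0.7, noise_sd = 35, spike_prob = 0.01,
               spike_height = 200, seed = 42)
  b <- sim_set(true_lh = 0.7, noise_sd = 35, spike_prob = 0.01,
               spike_height = 200, seed = 42)
  expect_identical(a$chromatograms, b$chromatograms)
  c <- sim_set(true_lh = 0.7, noise_sd = 35, seed = 43)
  expect_false(identical(a$chromatograms$intensity,
                         c$chromatograms$intensity))
})

test_that("cohorts replay identically and carry the manifest structure", {
  cfg <- cohort_sim_config(seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_equal(table(a$manifest$group)[["cancer"]], 14)
  expect_equal(table(a$manifest$group)[["non-cancer"]], 6)
  expect_equal(table(a$manifest$group)[["post-op"]], 7)
  expect_equal(sum(a$manifest$significance == "low_grade"), 6)
  expect_equal(sum(a$manifest$significance == "significant"), 5)
  expect_equal(dim(a$matrix), c(27L, 18L))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_sim_config(rho = 1), "rho")
  expect_error(cohort_sim_config(postop_psa_fraction = 0), "fraction")
  expect_error(cohort_sim_config(n_cancer = 5), "strata")
  expect_error(cohort_sim_config(missing_rate = 1), "missing_rate")
})

test_that("programmed within-protein correlation is recovered at n = 500", {
  mk <- data.frame(peptide = c("A1", "A2", "IVGGWECEK"),
                   protein = c("PROT", "PROT", "PSA"),
                   target_auc = c(0.5, 0.5, 0.5))
  cfg <- cohort_sim_config(n_cancer = 250, n_noncancer = 250, n_postop = 0,
                           markers = mk, rho = 0.6, secretion_sd = 0,
                           n_low_grade = 0, n_significant = 0,
                           sig_fold = numeric(0), missing_rate = 0, seed = 17)
  co <- simulate_cohort(cfg)
  r <- cor(log(co$matrix[, "A1"]), log(co$matrix[, "A2"]))
  expect_gt(r, 0.5)
  expect_lt(r, 0.7)
})

test_that("null markers give chance-level AUC and targeted markers recover it", {
  mk <- data.frame(peptide = c("M1", "IVGGWECEK"), protein = c("P1", "PSA"))
  # null: d = 0
  mk0 <- mk; mk0$target_auc <- c(0.5, 0.5)
  aucs0 <- vapply(1:200, function(i) {
    co <- simulate_cohort(cohort_sim_config(
      markers = mk0, n_postop = 0, n_low_grade = 0, n_significant = 0,
      sig_fold = numeric(0), missing_rate = 0, seed = 100 + i))
    mf <- co$manifest
    roc(co$matrix[, "M1"], as.character(mf$group))$auc
  }, numeric(1))
  expect_gt(mean(aucs0), 0.45)
  expect_lt(mean(aucs0), 0.55)

  # effect sized for a normalized AUC of 0.85, no secretion confounding
  mk1 <- mk; mk1$target_auc <- c(0.85, 0.5)
  aucs1 <- vapply(1:500, function(i) {
    co <- simulate_cohort(cohort_sim_config(
      markers = mk1, n_postop = 0, n_low_grade = 0, n_significant = 0,
      sig_fold = numeric(0), missing_rate = 0, secretion_sd = 0,
      seed = 5000 + i))
    mn <- normalize_to_psa(co$matrix)
    mf <- co$manifest[match(rownames(mn), co$manifest$sample_id), ]
    roc(mn[, "M1"], as.character(mf$group))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs1) - 0.85), 0.05)
})

test_that("the post-op PSA channel sits at the configured fraction", {
  # near-noiseless construction: the percentage is pinned at 1%
  mk <- data.frame(peptide = "IVGGWECEK", protein = "PSA")
  cfg <- cohort_sim_config(markers = mk, peptide_sd = 0.05, secretion_sd = 0,
                           postop_psa_fraction = 0.01, missing_rate = 0,
                           seed = 23)
  co <- simulate_cohort(cfg)
  psa <- lh_to_amount(co$matrix[, "IVGGWECEK"])$fmol_per_100ug
  pre <- psa[co$manifest$group != "post-op"]
  post <- psa[co$manifest$group == "post-op"]
  po <- psa_origin_summary(pre, post)
  expect_equal(po$pct_mean_headline, 1)
  expect_equal(po$pct_mean, 1, tolerance = 0.05)

  # at realistic noise the estimate is noisy but in the right decade
  cfg2 <- cohort_sim_config(markers = mk, missing_rate = 0, seed = 24)
  co2 <- simulate_cohort(cfg2)
  psa2 <- lh_to_amount(co2$matrix[, "IVGGWECEK"])$fmol_per_100ug
  po2 <- psa_origin_summary(psa2[co2$manifest$group != "post-op"],
                            psa2[co2$manifest$group == "post-op"])
  expect_gt(po2$pct_mean, 0.2)
  expect_lt(po2$pct_mean, 5)
})

test_that("chromatogram batches cover every matrix cell deterministically", {
  m <- matrix(c(0.5, 2, NA, 1), 2, 2,
              dimnames = list(c("S1", "S2"), c("AVIDDAFAR", "LPQTLSR")))
  class(m) <- c("marker_matrix", class(m))
  assay <- build_assay_table(data.frame(
    peptide = rep(c("AVIDDAFAR", "LPQTLSR"), each = 3),
    fragment = c("y7", "y6", "y5", "y5", "y4", "y6"),
    is_quantifier = rep(c(TRUE, FALSE, FALSE), 2)))
  b1 <- simulate_chromatogram_batch(m, assay, seed = 5)
  b2 <- simulate_chromatogram_batch(m, assay, seed = 5)
  expect_identical(b1, b2)
  key <- unique(b1[c("sample_id", "peptide")])
  expect_equal(nrow(key), 4L)
  expect_setequal(unique(b1$fragment[b1$peptide == "AVIDDAFAR"]),
                  c("y7", "y6", "y5"))
})
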