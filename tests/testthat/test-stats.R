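# Rank test, ROC machinery and concordance, each checked against an
# independent oracle (pair-counting enumeration, stats::wilcox.test, pROC).

test_that("rank_test matches the enumeration oracle on small datasets", {
  expect_equal(rank_test(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(rank_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  set.seed(123)
  for (rep in 1:40) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    if (n1 + n2 > 8) next
    # integer draws produce frequent ties
    a <- sample(1:5, n1, replace = TRUE)
    b <- sample(1:5, n2, replace = TRUE)
    rt <- rank_test(a, b)
    expect_equal(rt$U, oracle_u(a, b))
    expect_equal(rt$p_value, oracle_rank_p(a, b), tolerance = 1e-12)
  }
  expect_error(rank_test(numeric(0), 1:3), "non-missing")
})

test_that("rank_test agrees with wilcox.test exactly (small) and closely (large)", {
  set.seed(99)
  for (rep in 1:20) {
    a <- rnorm(sample(3:6, 1))   # continuous: no ties
    b <- rnorm(sample(3:6, 1))
    rt <- rank_test(a, b)
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(rt$U, unname(wt$statistic))
    expect_equal(rt$p_value, wt$p.value, tolerance = 1e-12)
  }
  for (rep in 1:10) {
    a <- rnorm(30, 0.3)
    b <- rnorm(30)
    rt <- rank_test(a, b)
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(rt$method, "normal")
    expect_equal(rt$p_value, wt$p.value, tolerance = 0.01)
  }
})

test_that("ROC handles separation, null data and degenerate input", {
  r <- roc(1:10, rep(c(FALSE, TRUE), each = 5), positive = TRUE)
  expect_equal(r$auc, 1)
  cut <- optimal_cutoff(r)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
  expect_false(cut$degenerate)

  set.seed(5)
  rnull <- roc(rnorm(400), rep(c(TRUE, FALSE), 200), positive = TRUE)
  expect_gt(rnull$auc, 0.42)
  expect_lt(rnull$auc, 0.58)

  rdeg <- roc(rep(1, 10), rep(c(TRUE, FALSE), 5), positive = TRUE)
  expect_true(optimal_cutoff(rdeg)$degenerate)
  expect_equal(optimal_cutoff(rdeg)$sensitivity +
                 optimal_cutoff(rdeg)$specificity, 1)

  expect_error(roc(1:5, rep(TRUE, 5), positive = TRUE), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney identity U/(n1*n2)", {
  set.seed(77)
  for (rep in 1:50) {
    n1 <- sample(3:8, 1)
    n0 <- sample(3:8, 1)
    scores <- c(sample(1:6, n1, replace = TRUE) + 0.5 * rbinom(n1, 1, 0.5),
                sample(1:6, n0, replace = TRUE))
    pos <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc(scores, pos, positive = TRUE)
    expect_equal(r$auc, oracle_auc(scores, pos), tolerance = 1e-12)
    rt <- rank_test(scores[pos], scores[!pos])
    expect_equal(r$auc, rt$U / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (rep in 1:10) {
    scores <- c(rnorm(12, 1), rnorm(9))
    labels <- rep(c(1, 0), c(12, 9))
    r <- roc(scores, labels)
    pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
    # same DeLong variance; the interval itself is logit-scaled here
    expect_equal(r$auc_se^2, as.numeric(pROC::var(pr, method = "delong")),
                 tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  scores <- rlnorm(30)
  pos <- rbinom(30, 1, 0.5) == 1
  pos[1:2] <- c(TRUE, FALSE)
  a0 <- roc(scores, pos, positive = TRUE)$auc
  expect_equal(roc(log(scores), pos, positive = TRUE)$auc, a0)
  expect_equal(roc(scores^3, pos, positive = TRUE)$auc, a0)
  expect_equal(roc(-1 / scores, pos, positive = TRUE)$auc, a0)
})

test_that("direction auto flips an anti-concordant marker and records it", {
  scores <- 1:10
  pos <- rep(c(TRUE, FALSE), each = 5)   # low scores are positive
  fixed <- roc(scores, pos, positive = TRUE)
  expect_equal(fixed$auc, 0)
  auto <- roc(scores, pos, positive = TRUE, direction = "auto")
  expect_equal(auto$auc, 1)
  expect_true(auto$flipped)
})

test_that("optimal cutoff matches an exhaustive threshold scan", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.9)
  pos <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  r <- roc(scores, pos, positive = TRUE)
  cut <- optimal_cutoff(r)
  grid <- sort(unique(c(scores - 1e-9, scores + 1e-9)))
  sums <- vapply(grid, function(t)
    mean(scores[pos] >= t) + mean(scores[!pos] < t), numeric(1))
  expect_equal(cut$sensitivity + cut$specificity, max(sums),
               tolerance = 1e-12)
})

test_that("DeLong intervals cover the true binormal AUC at small n", {
  set.seed(2024)
  auc_true <- 0.75
  d <- sqrt(2) * qnorm(auc_true)
  cover <- vapply(1:500, function(i) {
    sc <- c(rnorm(14, d), rnorm(6))
    r <- roc(sc, rep(c(TRUE, FALSE), c(14, 6)), positive = TRUE)
    r$ci[1] <= auc_true && auc_true <= r$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("concordance reports r-squared per protein pair with reasons", {
  set.seed(14)
  x <- rlnorm(30)
  m <- cbind(P1a = x, P1b = 2 * x, P2a = rlnorm(30), FLAT = rep(1, 30))
  rownames(m) <- paste0("S", 1:30)
  pm <- c(P1a = "A", P1b = "A", P2a = "B", FLAT = "A")
  cr <- concordance(m, pm)
  exact <- cr[cr$peptide_a == "P1a" & cr$peptide_b == "P1b", ]
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_false(exact$discordant)
  flat <- cr[cr$peptide_b == "FLAT" | cr$peptide_a == "FLAT", ]
  expect_true(all(flat$reason == "zero variance"))
  expect_false("P2a" %in% c(cr$peptide_a, cr$peptide_b))  # single peptide
})

test_that("programmed correlation is recovered in the sampling band", {
  set.seed(90)
  rho <- 0.8
  n <- 200
  z <- rnorm(n)
  a <- exp(sqrt(rho) * z + sqrt(1 - rho) * rnorm(n))
  b <- exp(sqrt(rho) * z + sqrt(1 - rho) * rnorm(n))
  m <- cbind(A1 = a, A2 = b)
  rownames(m) <- paste0("S", 1:n)
  cr <- concordance(m, c(A1 = "A", A2 = "A"))
  # correlation is programmed on the log scale; check there
  r2 <- cor(log(a), log(b))^2
  expect_equal(cr$r_squared, cor(a, b)^2, tolerance = 1e-12)
  expect_gt(r2, rho^2 - 0.1)
  expect_lt(r2, rho^2 + 0.1)
})
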