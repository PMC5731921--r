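# Per-peptide L/H quantification with QC gating, on simulated sets with known
# ground truth and on hand-built traces sitting exactly at the gates.

test_that("noiseless simulation recovers the true L/H almost exactly", {
  s <- sim_set(true_lh = 0.5, noise_sd = 0, seed = 1)
  q <- quantify_group(s$chromatograms, toy_assay())
  expect_true(q$detectable)
  expect_lt(abs(q$lh - 0.5) / 0.5, 0.001)
  expect_equal(unname(q$expected_ratios), c(0.5, 0.3, 0.2), tolerance = 1e-6)
  expect_equal(unname(q$observed_ratios), c(0.5, 0.3, 0.2), tolerance = 1e-6)
})

test_that("L/H is invariant to rescaling all intensities of the sample", {
  s <- sim_set(true_lh = 0.8, noise_sd = 30, seed = 11)
  q1 <- quantify_group(s$chromatograms, toy_assay())
  scaled <- s$chromatograms
  scaled$intensity <- scaled$intensity * 7.3
  q2 <- quantify_group(scaled, toy_assay())
  expect_true(q1$detectable && q2$detectable)
  expect_equal(q2$lh, q1$lh, tolerance = 1e-9)
  expect_equal(q2$snr, q1$snr, tolerance = 1e-9)
})

test_that("a light peak 30 s from the heavy standard fails the RT match", {
  s <- sim_set(true_lh = 1, noise_sd = 0, light_rt_shift = 30, seed = 2)
  q <- quantify_group(s$chromatograms, toy_assay())
  expect_false(q$detectable)
  expect_equal(q$reason, "rt_mismatch")
  expect_true(is.na(q$lh))
})

test_that("quantifier S/N below 10 blocks detectability with reason low_snr", {
  # hand-built: light apex 99 with a background point at 10 -> S/N 9.9
  times <- seq(240, 360, 1)
  heavy_amp <- c(1000, 600, 400)
  rows <- list()
  for (i in 1:3) {
    h <- heavy_amp[i] * exp(-(times - 300)^2 / (2 * 16))
    l <- 0.099 * h
    if (i == 1) l[times == 315] <- 10   # outside peak, inside 15 s window
    rows[[length(rows) + 1]] <- data.frame(sample_id = "S1",
      peptide = "PEPTIDEK", fragment = c("y6", "y5", "y4")[i],
      label = "heavy", time_sec = times, intensity = h)
    rows[[length(rows) + 1]] <- data.frame(sample_id = "S1",
      peptide = "PEPTIDEK", fragment = c("y6", "y5", "y4")[i],
      label = "light", time_sec = times, intensity = l)
  }
  chrom <- do.call(rbind, rows)
  q <- quantify_group(chrom, toy_assay())
  expect_false(q$detectable)
  expect_equal(q$reason, "low_snr")
  expect_equal(q$snr, 9.9, tolerance = 0.01)
})

test_that("a co-eluting contaminant marks the peptide interfered", {
  s <- sim_set(true_lh = 1, noise_sd = 10, seed = 3,
               interference = list(transition = 2, rel_height = 1,
                                   rt_offset = 0))
  q <- quantify_group(s$chromatograms, toy_assay())
  expect_true(any(q$interference_flags))
  # doubling transition 2 distorts the whole normalized vector, including the
  # quantifier, so the peptide is gated out
  expect_false(q$detectable)
  expect_equal(q$reason, "interfered")
})

test_that("a missing heavy standard aborts the peptide", {
  s <- sim_set(true_lh = 1, noise_sd = 0, seed = 4)
  ch <- s$chromatograms
  ch <- ch[!(ch$label == "heavy" & ch$fragment == "y5"), ]
  expect_error(quantify_group(ch, toy_assay()), "y5")
})

test_that("S/N falls monotonically with injected noise amplitude", {
  snrs <- vapply(c(10, 40, 100, 250, 600), function(nsd) {
    s <- sim_set(true_lh = 0.3, noise_sd = nsd, seed = 99)
    q <- quantify_group(s$chromatograms, toy_assay())
    q$snr
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("L/H recovery across the ratio grid stays within 10% median error", {
  errs <- unlist(lapply(c(0.01, 0.1, 1, 10), function(lh) {
    vapply(1:5, function(r) {
      nsd <- 0.05 * 1e4 * min(1, lh)  # 5% of the weaker channel's apex
      s <- sim_set(true_lh = lh, noise_sd = nsd, seed = 1000 + r)
      q <- quantify_group(s$chromatograms, toy_assay())
      est <- q$light_areas[[q$quantifier]] / q$heavy_areas[[q$quantifier]]
      abs(est - lh) / lh
    }, numeric(1))
  }))
  expect_lt(stats::median(errs), 0.10)
})

test_that("marker matrices assemble with reason codes and round-trip CSV", {
  qs <- list(
    quantify_group(sim_set(true_lh = 0.5, noise_sd = 0,
                           seed = 5)$chromatograms, toy_assay()),
    quantify_group(sim_set(true_lh = 2, noise_sd = 0, light_rt_shift = 30,
                           seed = 6)$chromatograms, toy_assay())
  )
  qs[[2]]$sample_id <- "S2"
  m <- marker_matrix(qs)
  expect_equal(dim(m), c(2L, 1L))
  expect_true(is.finite(m["S1", "PEPTIDEK"]))
  expect_true(is.na(m["S2", "PEPTIDEK"]))
  expect_equal(attr(m, "reasons")$reason, "rt_mismatch")

  path <- tempfile(fileext = ".csv")
  write_marker_matrix(m, path)
  back <- read_marker_matrix(path)
  expect_equal(unclass(back)[, 1], unclass(m)[, 1], tolerance = 1e-12)
  expect_equal(attr(back, "reasons")$reason, "rt_mismatch")
})
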