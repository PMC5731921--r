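# Peak detection, integration, S/N and interference flagging on constructed
# traces with known geometry.

test_that("detect_peak finds a Gaussian apex on a quiet baseline", {
  tr <- gaussian_trace(center = 20, amp = 1000, times = seq(0, 40, 0.5))
  pk <- detect_peak(tr$time, tr$intensity, expected_rt = 20)
  expect_true(pk$found)
  expect_equal(pk$apex_time, 20)
  expect_equal(pk$apex_intensity, 1000)
  expect_lt(pk$left, 20)
  expect_gt(pk$right, 20)
})

test_that("of two equal peaks the one nearer the expected RT wins", {
  times <- seq(0, 40, 0.5)
  two <- gaussian_trace(15, 1000, 1.5, times)$intensity +
    gaussian_trace(25, 1000, 1.5, times)$intensity
  pk <- detect_peak(times, two, expected_rt = 24)
  expect_equal(pk$apex_time, 25)
  pk2 <- detect_peak(times, two, expected_rt = 16)
  expect_equal(pk2$apex_time, 15)
})

test_that("degenerate traces are handled", {
  times <- seq(0, 40, 1)
  pk <- detect_peak(times, rep(0, length(times)), expected_rt = 20)
  expect_false(pk$found)
  expect_error(detect_peak(times, rep(0, length(times)), expected_rt = 99),
               "outside trace time range")
  expect_error(detect_peak(c(1, 1, 2), c(0, 0, 0), expected_rt = 1),
               "strictly increasing")
  expect_error(detect_peak(numeric(0), numeric(0), expected_rt = 1),
               "at least 2")
  expect_warning(detect_peak(c(0, 1, 2, 10, 11), c(0, 1, 5, 1, 0),
                             expected_rt = 2), "irregular sampling")
})

test_that("integration subtracts the boundary baseline and recovers areas", {
  # near-rectangle, height 10 over 10 s on a zero baseline -> area 100
  times <- seq(0, 30, 0.01)
  rect <- ifelse(times >= 10 & times <= 20, 10, 0)
  pk <- detect_peak(times, rect, expected_rt = 15)
  expect_equal(integrate_area(times, rect, pk), 100, tolerance = 0.005)

  # same rectangle standing on baseline 5 -> net area 50
  rect5 <- ifelse(times >= 10 & times <= 20, 10, 5)
  pk5 <- detect_peak(times, rect5, expected_rt = 15)
  expect_equal(integrate_area(times, rect5, pk5), 50, tolerance = 0.01)

  # unit-area Gaussian sampled at 0.5 s: the trapezoidal result must match
  # the analytic integral over the detected boundaries minus the analytic
  # baseline trapezoid (the oracle uses pnorm/dnorm, not the sampled trace)
  sigma <- 2
  times <- seq(0, 60, 0.5)
  y <- stats::dnorm(times, 30, sigma)
  pk <- detect_peak(times, y, expected_rt = 30)
  closed <- (stats::pnorm(pk$right, 30, sigma) -
               stats::pnorm(pk$left, 30, sigma)) -
    (pk$right - pk$left) *
      (stats::dnorm(pk$left, 30, sigma) + stats::dnorm(pk$right, 30, sigma)) / 2
  expect_equal(integrate_area(times, y, pk), closed, tolerance = 0.02)
  expect_gt(closed, 0.85)   # most of the unit mass survives the truncation
})

test_that("S/N uses the highest background within 15 s, outside the peak", {
  times <- seq(0, 60, 1)
  y <- rep(0, length(times))
  y[times == 29] <- 500; y[times == 30] <- 1000; y[times == 31] <- 500
  y[times == 42] <- 100   # inside the 15 s window, outside the peak
  y[times == 50] <- 900   # beyond 15 s: must be ignored
  pk <- detect_peak(times, y, expected_rt = 30)
  sn <- signal_to_noise(times, y, pk)
  expect_equal(sn$noise_level, 100)
  expect_equal(sn$snr, 10)   # exactly at the quantifiability boundary

  # zero background -> finite cap
  y2 <- rep(0, length(times))
  y2[times == 29] <- 500; y2[times == 30] <- 1000; y2[times == 31] <- 500
  pk2 <- detect_peak(times, y2, expected_rt = 30)
  sn2 <- signal_to_noise(times, y2, pk2)
  expect_equal(sn2$snr, srm_config()$snr_cap)
})

test_that("heavy-standard ratios normalize and require all transitions", {
  r <- expected_transition_ratios(c(t1 = 100, t2 = 50, t3 = 25))
  expect_equal(sum(r), 1)
  expect_equal(unname(r), c(4, 2, 1) / 7, tolerance = 1e-12)
  expect_equal(unname(expected_transition_ratios(c(a = 3, b = 3, c = 3))),
               rep(1 / 3, 3))
  expect_error(expected_transition_ratios(c(t1 = 100, t2 = NA, t3 = 25)),
               "t2")
})

test_that("interference flags fire on relative ratio deviations", {
  expected <- c(4, 2, 1) / 7
  none <- flag_interference(expected, expected)
  expect_false(any(none$flags))
  expect_equal(none$dot_product, 1, tolerance = 1e-12)

  # transition 2 doubled, then renormalized: its deviation is the largest
  obs <- expected
  obs[2] <- obs[2] * 2
  obs <- obs / sum(obs)
  fl <- flag_interference(obs, expected, threshold = 0.2)
  expect_true(fl$flags[2])
  expect_equal(which.max(fl$deviation), 2L)
  expect_lt(fl$dot_product, 1)

  expect_false(any(flag_interference(obs, expected, threshold = Inf)$flags))
  expect_error(flag_interference(obs, c(0, 0.5, 0.5)), "positive")
  expect_error(flag_interference(obs[1:2], expected), "length")
})
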