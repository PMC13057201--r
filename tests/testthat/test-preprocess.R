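test_that("neuropil correction applies the scaled subtraction", {
  expect_equal(neuropil_correct(100, 20, 0.7), 86)
  x <- c(3, 5, 8)
  expect_equal(neuropil_correct(x, rep(0, 3)), x)
  expect_equal(neuropil_correct(0.7 * x, x, 0.7), rep(0, 3))
  expect_error(neuropil_correct(1:3, 1:4), "length")
})

test_that("per-trial dF/F uses the trial's own baseline and flags bad F0", {
  w <- trial_window(baseline_frames = 4, stim_frames = 3, response_frames = 2)
  const <- rep(5, 60)
  d <- compute_dff(const, c(10, 30), w)
  expect_true(all(d$dff == 0))
  expect_true(all(d$valid))

  tr <- rep(2, 60); tr[31:40] <- 3
  d2 <- compute_dff(tr, 30, w)
  expect_equal(d2$dff[d2$frame_offset >= 0 & d2$frame_offset < 3], rep(0.5, 3))

  zero <- rep(0, 60)
  d3 <- compute_dff(zero, 30, w)
  expect_false(any(d3$valid))
  expect_true(all(is.na(d3$dff)))

  # ratio normalisation: invariant to positive scaling of the trace
  d4 <- compute_dff(7 * tr, 30, w)
  expect_equal(d4$dff, d2$dff)
  expect_error(compute_dff(const, c(30, 10), w), "increasing")
})

test_that("motion flags threshold displacements and dilate around epochs", {
  expect_false(any(detect_motion_epochs(matrix(0, 50, 2), threshold_px = 2)))

  shifts <- rep(0, 50); shifts[25] <- 10
  flags <- detect_motion_epochs(shifts, threshold_px = 2, margin = 2)
  expect_identical(which(flags), 23:27)

  # synthetic epochs recovered with high overlap
  truth <- rep(FALSE, 3000)
  starts <- c(200, 900, 1500, 2200, 2700)
  for (s in starts) truth[s:(s + 59)] <- TRUE
  shifts <- with_seed_local(2, abs(rnorm(3000, 0, 0.2)))
  shifts[truth] <- shifts[truth] + 5
  got <- detect_motion_epochs(shifts, threshold_px = 2, margin = 2)
  jaccard <- sum(got & truth) / sum(got | truth)
  expect_gte(jaccard, 0.9)
})

test_that("trial gating demands a clean baseline and 70% stable stimulation", {
  w <- trial_window(baseline_frames = 30, stim_frames = 7, response_frames = 5)
  onsets <- c(40, 200, 360)
  none <- rep(FALSE, 500)
  expect_identical(select_trials(none, onsets, w), 1:3)

  one_base <- none; one_base[30] <- TRUE   # frame 29 (0-based) in trial 1 baseline
  expect_identical(select_trials(one_base, onsets, w), 2:3)

  two_stim <- none; two_stim[c(202, 204)] <- TRUE   # 2/7 flagged: 71% stable
  expect_identical(select_trials(two_stim, onsets, w), 1:3)
  three_stim <- none; three_stim[c(202, 204, 206)] <- TRUE  # 57% stable
  expect_identical(select_trials(three_stim, onsets, w), c(1L, 3L))
})

test_that("adding motion flags never adds trials (monotonicity)", {
  w <- trial_window(baseline_frames = 10, stim_frames = 7, response_frames = 3)
  onsets <- seq(20, 460, by = 40)
  base <- with_seed_local(3, runif(500) < 0.05)
  more <- base | with_seed_local(4, runif(500) < 0.05)
  expect_true(all(select_trials(more, onsets, w) %in% select_trials(base, onsets, w)))
})

test_that("SNR matches the closed-form white-noise prediction", {
  # Oracle: for iid N(0,1) input, p95 - p5 = 2 * qnorm(0.95); the zero-phase
  # 4th-order Butterworth high-pass multiplies the noise sd by
  # sqrt(mean |H|^4) with |H|^2 = 1 / (1 + (tan(wc/2) / tan(w/2))^8).
  fs <- 30; fc <- 10
  wc <- 2 * pi * fc / fs
  w <- seq(1e-4, pi - 1e-4, length.out = 20000)
  h2 <- 1 / (1 + (tan(wc / 2) / tan(w / 2))^8)
  gain <- sqrt(mean(h2^2))
  expected <- 2 * qnorm(0.95) / gain

  tr <- with_seed_local(5, rnorm(60000))
  snr <- compute_snr(tr, frame_rate = fs, cutoff_hz = fc)
  expect_lt(abs(snr - expected) / expected, 0.05)

  # invariant to an additive offset
  expect_equal(compute_snr(tr + 100, frame_rate = fs), snr)
  expect_error(compute_snr(rep(1, 100)), "degenerate")
})

test_that("preprocess_traces gates trials and tabulates dF/F per ROI", {
  e <- generate_experiment(small_config())
  tr <- experiment_traces(e, sessions = 1)
  trials <- dplyr::filter(experiment_trials(e), session == 1)
  out <- preprocess_traces(tr, trials)
  expect_setequal(unique(out$dff$roi_id), unique(tr$roi_id))
  expect_equal(nrow(out$inclusion), nrow(trials))
  expect_true(any(out$inclusion$included))
  expect_true(all(out$snr$snr > 0))
})
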