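make_trace <- function(y, frame_rate, detrend = TRUE)
  chamberbeat:::trace_from_signal(y, frame_rate, detrend = detrend)

test_that("heartbeat traces oscillate at the true chamber frequency", {
  sim <- generate_heart_video(heart_sim_params(freq_atrium = 2, freq_ventricle = 2,
                                               seed = 6))
  masks <- masks_from_truth(sim)
  tr <- extract_heartbeat_trace(sim$stack, masks, "atrium")
  expect_true(all(tr$combined_signal >= 0 & tr$combined_signal <= 1))
  expect_length(tr$combined_signal, length(sim$stack$frames))
  # dominant period 0.5 s by an independent DFT oracle
  expect_equal(oracle_dft_peak_freq(tr$combined_signal, 30), 2, tolerance = 1 / 6)
})

test_that("empty masks and constant signals are flagged, not fatal downstream", {
  sim <- generate_heart_video(heart_sim_params(duration = 1, seed = 6))
  n <- length(sim$stack$frames)
  d <- dim(sim$stack$frames[[1]])
  empty <- make_mask_series(replicate(n, matrix(FALSE, d[1], d[2]), simplify = FALSE),
                            sim$truth$masks$ventricle, 2.5)
  expect_error(extract_heartbeat_trace(sim$stack, empty, "atrium"),
               class = "cb_empty_mask_error")

  # no contraction, no noise: constant trace -> flagged -> fit failure result
  flat <- generate_heart_video(heart_sim_params(contraction_atrium = 0,
                                                contraction_ventricle = 0,
                                                noise_sd = 0, duration = 1,
                                                seed = 6))
  trf <- extract_heartbeat_trace(flat$stack, masks_from_truth(flat), "atrium")
  expect_true(trf$constant)
  fit <- fit_sine(trf, 30)
  expect_true(fit$failed)
  expect_true(is.na(fit$freq))
})

test_that("sine fitting recovers clean frequencies and beats the score floor", {
  t <- seq(0, 6 - 1 / 30, by = 1 / 30)
  tr <- make_trace(sin(2 * pi * 2.5 * t), 30)
  fit <- fit_sine(tr, 30)
  expect_false(fit$failed)
  expect_equal(fit$freq, 2.5, tolerance = 0.05 / 2.5)
  expect_gt(fit$fit_score, 0.99)
  # on an undistorted stationary sine, ties go to the full-length fit
  fit2 <- fit_sine(make_trace(sin(2 * pi * 2.5 * t), 30, detrend = FALSE), 30)
  expect_false(fit2$used_truncated)

  expect_true(fit_sine(make_trace(rep(1, 60), 10), 10)$failed)
  expect_error(fit_sine(make_trace(sin(1:10), 10), 10),
               class = "cb_precondition_error")
})

test_that("the truncated-signal refit wins when the beat collapses mid-recording", {
  # 2 Hz for the first quarter, then silence with faint noise
  t <- seq(0, 8 - 1 / 30, by = 1 / 30)
  y <- ifelse(t < 2, sin(2 * pi * 2 * t), 0)
  set.seed(5)
  y <- y + rnorm(length(y), 0, 0.02)
  fit <- fit_sine(make_trace(y, 30), 30)
  expect_true(fit$used_truncated)
  expect_equal(fit$freq, 2, tolerance = 0.1 / 2)
  # oracle confirms: quarter-signal grid search also lands at 2 Hz
  nq <- floor(length(y) / 4)
  expect_equal(oracle_grid_freq(y[1:nq], t[1:nq]), 2, tolerance = 0.05)
})

test_that("FFT frequency picks the dominant non-DC bin", {
  t <- (0:35) / 6
  expect_equal(fft_frequency(make_trace(cos(2 * pi * t), 6), 6), 1)  # exactly on-bin
  t2 <- seq(0, 12 - 1 / 12, by = 1 / 12)
  y2 <- sin(2 * pi * 2 * t2) + 0.5 * sin(2 * pi * 4 * t2)
  expect_equal(fft_frequency(make_trace(y2, 12), 12),
               oracle_dft_peak_freq(y2, 12))
  expect_equal(fft_frequency(make_trace(y2, 12), 12), 2)
  expect_true(is.na(fft_frequency(make_trace(rep(3, 16), 12), 12)))
  expect_error(fft_frequency(make_trace(sin(1:5), 6), 6),
               class = "cb_precondition_error")
})

test_that("autocorrelation separates periodic signals from noise", {
  t <- seq(0, 4 - 1 / 15, by = 1 / 15)
  expect_gt(autocorrelation_score(make_trace(sin(2 * pi * 1.5 * t), 15)), 0.95)
  expect_equal(autocorrelation_score(make_trace(rep(2, 20), 15)), 0)
  noise_scores <- vapply(1:100, function(s) {
    set.seed(s)
    autocorrelation_score(make_trace(rnorm(60), 10, detrend = FALSE))
  }, numeric(1))
  # Monte-Carlo calibrated: white noise of length 60 almost always scores
  # below 0.5 and never approaches the periodic regime
  expect_gte(mean(noise_scores < 0.5), 0.95)
  expect_lt(max(noise_scores), 0.8)
})

test_that("frequency estimates are invariant to intensity rescaling", {
  sim <- generate_heart_video(heart_sim_params(seed = 17, duration = 3))
  masks <- masks_from_truth(sim)
  scaled <- frame_stack(lapply(sim$stack$frames, function(m) m * 7.3),
                        sim$stack$frame_rate, sim$stack$pixel_size)
  f1 <- estimate_frequency(extract_heartbeat_trace(sim$stack, masks, "atrium"), 30)
  f2 <- estimate_frequency(extract_heartbeat_trace(scaled, masks, "atrium"), 30)
  expect_equal(f1$freq, f2$freq)
  expect_equal(f1$fft_freq, f2$fft_freq)
})

test_that("sine fits track the grid-search oracle within one FFT bin across seeds", {
  set.seed(88)
  freqs <- runif(25, 0.5, 4)
  for (i in seq_along(freqs)) {
    n <- 90; fr <- 15
    t <- (seq_len(n) - 1) / fr
    set.seed(1000 + i)
    y <- sin(2 * pi * freqs[i] * t + runif(1, 0, 2 * pi)) + rnorm(n, 0, 1 / 3)
    fit <- fit_sine(make_trace(y, fr), fr)
    expect_equal(fit$freq, oracle_grid_freq(y, t), tolerance = (fr / n) / fit$freq)
  }
})

test_that("sine and FFT agree within one bin for clean on-bin sines", {
  fr <- 12; n <- 72
  t <- (seq_len(n) - 1) / fr
  for (f in c(1, 2, 3)) {
    tr <- make_trace(sin(2 * pi * f * t), fr)
    est <- estimate_frequency(tr, fr)
    expect_equal(est$fft_freq, f)
    expect_lte(abs(est$freq - est$fft_freq), fr / n)
  }
})

test_that("at 6 f/s the FFT stays on-bin where sine fitting may alias", {
  # frame-rate guidance: FFT is the reliable route at 6 f/s
  for (f in c(1, 1.5, 2, 2.5)) {
    sim <- generate_heart_video(heart_sim_params(freq_atrium = f,
                                                 freq_ventricle = f,
                                                 frame_rate = 6, seed = 23))
    tr <- extract_heartbeat_trace(sim$stack, masks_from_truth(sim), "atrium")
    expect_equal(fft_frequency(tr, 6), f)
  }
})
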