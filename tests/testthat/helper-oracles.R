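# Independent oracles and fixture builders used across the suite.

# dense grid-search frequency oracle: correlation-maximizing sine frequency,
# with the linear sub-problem solved by lsfit (independent of the package's
# refinement path)
oracle_grid_freq <- function(y, t, grid = seq(0.25, 6, by = 0.001)) {
  best_f <- NA_real_; best_r <- -Inf
  for (f in grid) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    fit <- stats::lsfit(X, y)
    yy <- y - fit$residuals
    if (stats::sd(yy) < 1e-12) next
    r <- stats::cor(y, yy)
    if (r > best_r) { best_r <- r; best_f <- f }
  }
  best_f
}

# naive O(n^2) DFT magnitude oracle (independent of stats::fft)
oracle_dft_peak_freq <- function(y, frame_rate) {
  n <- length(y)
  y <- y - mean(y)
  ks <- seq_len(n %/% 2)
  mags <- vapply(ks, function(k) {
    w <- -2 * pi * k * (seq_len(n) - 1) / n
    sqrt(sum(y * cos(w))^2 + sum(y * sin(w))^2)
  }, numeric(1))
  ks[which.max(mags)] * frame_rate / n
}

# brute-force 4-connected component labeling oracle (flood fill)
oracle_label_components <- function(bw) {
  lab <- matrix(0L, nrow(bw), ncol(bw))
  cur <- 0L
  for (start in which(bw)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(bw)
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
      for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        if (d[1] < 1 || d[1] > nr || d[2] < 1 || d[2] > ncol(bw)) next
        q <- (d[2] - 1) * nr + d[1]
        if (bw[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# draw an ellipse of intensity `value` onto matrix m
draw_ellipse <- function(m, cx, cy, a, b, value) {
  X <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m))
  Y <- matrix(rep(seq_len(nrow(m)), ncol(m)), nrow(m))
  m[((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1] <- value
  m
}

make_mask_series <- function(atrium, ventricle, pixel_size) {
  structure(list(atrium = atrium, ventricle = ventricle,
                 pixel_size = pixel_size,
                 misses = c(atrium = 0L, ventricle = 0L)),
            class = "chamber_mask_series")
}

# package a ground-truth mask set as a chamber_mask_series
masks_from_truth <- function(sim) {
  make_mask_series(sim$truth$masks$atrium, sim$truth$masks$ventricle,
                   sim$stack$pixel_size)
}

# full pipeline on a generated video; returns record, fits and sim
run_sim_pipeline <- function(params, ...) {
  sim <- generate_heart_video(params)
  roi <- detect_heart_roi(sim$stack)
  seeds <- seeds_from_truth(sim$truth, roi)
  res <- analyze_heart(sim$stack, seeds, roi = roi, ...)
  c(res, list(sim = sim))
}

# a synthetic pulse train with beats at the given times (seconds)
pulse_trace <- function(beat_times, duration, frame_rate, width = 0.05) {
  t <- (seq_len(round(duration * frame_rate)) - 1) / frame_rate
  y <- rowSums(vapply(beat_times,
                      function(b) exp(-(t - b)^2 / (2 * width^2)),
                      numeric(length(t))))
  chamberbeat:::trace_from_signal(y, frame_rate, detrend = FALSE)
}
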