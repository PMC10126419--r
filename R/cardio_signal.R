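#' Extract a per-chamber heartbeat trace
#'
#' The chamber's raw heartbeat signal combines two per-frame measurements:
#' the sum of pixel intensities inside the chamber mask, and the chamber
#' area. Each is detrended by removing a least-squares line (compensating
#' photobleaching and focus drift) and min--max normalized to `[0, 1]`; the
#' combined signal is their mean. A signal that is constant after
#' detrending is flagged so downstream fits report failure instead of
#' crashing.
#'
#' @param stack a [frame_stack()].
#' @param masks a `chamber_mask_series` from [segment_chambers()].
#' @param chamber `"atrium"` or `"ventricle"`.
#' @return A `chamber_trace`: `time` (s), `intensity_signal`, `area_signal`,
#'   `combined_signal` (all in `[0, 1]`), `constant` flag, `chamber`.
#' @export
extract_heartbeat_trace <- function(stack, masks, chamber = c("atrium", "ventricle")) {
  chamber <- match.arg(chamber)
  stopifnot(inherits(stack, "frame_stack"), inherits(masks, "chamber_mask_series"))
  series <- masks[[chamber]]
  if (length(series) != length(stack$frames))
    cb_stop("cb_alignment_error", "mask series does not match stack length")
  counts <- vapply(series, sum, numeric(1))
  if (all(counts == 0))
    cb_stop("cb_empty_mask_error", "all %s masks are empty; no pixels to sum", chamber)
  intens <- vapply(seq_along(series), function(i) sum(stack$frames[[i]][series[[i]]]),
                   numeric(1))
  area <- counts * masks$pixel_size^2
  n <- length(intens)
  ii <- detrend_linear(intens)
  aa <- detrend_linear(area)
  tol <- 1e-9 * max(1, abs(mean(intens)), abs(mean(area)))
  constant <- (diff(range(ii)) <= tol) && (diff(range(aa)) <= tol)
  ni <- minmax_scale(ii)
  na <- minmax_scale(aa)
  structure(list(
    time = (seq_len(n) - 1) / stack$frame_rate,
    intensity_signal = ni, area_signal = na,
    combined_signal = (ni + na) / 2,
    constant = constant, chamber = chamber
  ), class = "chamber_trace")
}

# build a chamber_trace directly from a 1-D signal (brightfield, tests)
trace_from_signal <- function(y, frame_rate, detrend = TRUE) {
  if (detrend) y <- detrend_linear(y)
  constant <- diff(range(y)) <= 1e-9 * max(1, abs(mean(y)))
  yn <- minmax_scale(y)
  structure(list(time = (seq_along(y) - 1) / frame_rate,
                 intensity_signal = yn, area_signal = yn, combined_signal = yn,
                 constant = constant, chamber = "signal"),
            class = "chamber_trace")
}

sine_fail <- function(reason) {
  structure(list(freq = NA_real_, amplitude = NA_real_, phase = NA_real_,
                 offset = NA_real_, fit_score = NA_real_,
                 used_truncated = FALSE, failed = TRUE, reason = reason),
            class = "sine_fit")
}

# linear least squares of y on {sin(2*pi*f*t), cos(2*pi*f*t), 1} at fixed f
harmonic_ls <- function(f, t, y) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t), 1)
  co <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, 3))
  if (anyNA(co)) return(list(sse = Inf, score = -Inf, coef = co))
  fit <- X %*% co
  sc <- if (stats::sd(fit) < 1e-12) -Inf else stats::cor(y, fit)
  list(sse = sum((y - fit)^2), score = sc, coef = co)
}

fit_sine_window <- function(t, y, f_lo, f_hi, n_starts) {
  starts <- seq(f_lo, f_hi, length.out = n_starts)
  spacing <- if (n_starts > 1) diff(starts[1:2]) else (f_hi - f_lo)
  best <- list(score = -Inf)
  for (f0 in starts) {
    opt <- stats::optimize(function(f) harmonic_ls(f, t, y)$sse,
                           c(max(1e-3, f0 - spacing), f0 + spacing), tol = 1e-7)
    cand <- harmonic_ls(opt$minimum, t, y)
    if (is.finite(cand$score) && cand$score > best$score) {
      best <- cand
      best$freq <- opt$minimum
    }
  }
  best
}

#' Fit a sine to a heartbeat trace
#'
#' Fits `y(t) = A sin(2 pi f t + phi) + c` by seeding 30 candidate
#' frequencies uniformly over `[0.25, min(6, frame_rate / 2)]` 1/s
#' (increasing-frequency search covering embryonic zebrafish heart rates up
#' to 360 beats/min) and locally refining each by least squares; for fixed
#' `f` the remaining parameters are solved exactly, and `f` is refined
#' within one seed spacing. The candidate maximizing the Pearson
#' correlation between raw and fitted signal wins. The whole procedure is
#' repeated on the first quarter of the trace (guarding against unstable
#' signals); whichever fit scores higher on its own support is returned,
#' with ties going to the full-length fit.
#'
#' @param trace a `chamber_trace` (needs >= 12 samples).
#' @param frame_rate frames per second.
#' @param n_starts number of candidate starting frequencies (default 30).
#' @param min_fit_score correlation floor below which the fit is reported
#'   as failed (default 0.1).
#' @return A `sine_fit`: `freq` (1/s, >= 0), `amplitude`, `phase` (rad),
#'   `offset`, `fit_score` (Pearson r), `used_truncated`, `failed`.
#' @export
fit_sine <- function(trace, frame_rate, n_starts = 30L, min_fit_score = 0.1) {
  y <- trace$combined_signal
  t <- trace$time
  if (length(y) < 12)
    cb_stop("cb_precondition_error", "sine fitting needs >= 12 samples, got %d", length(y))
  if (isTRUE(trace$constant) || stats::sd(y) < 1e-12)
    return(sine_fail("constant signal"))
  f_hi <- min(6, frame_rate / 2)
  full <- fit_sine_window(t, y, 0.25, f_hi, n_starts)
  nq <- floor(length(y) / 4)
  trunc_fit <- if (nq >= 8 && stats::sd(y[seq_len(nq)]) > 1e-12)
    fit_sine_window(t[seq_len(nq)], y[seq_len(nq)], 0.25, f_hi, n_starts)
  else list(score = -Inf)
  # ties (within numerical noise) go to the full-length fit: more data
  use_trunc <- is.finite(trunc_fit$score) &&
    trunc_fit$score > full$score + 1e-6
  best <- if (use_trunc) trunc_fit else full
  if (!is.finite(best$score) || best$score < min_fit_score)
    return(sine_fail(sprintf("best fit score %.3g below threshold", best$score)))
  a <- best$coef[1]; b <- best$coef[2]
  structure(list(freq = best$freq, amplitude = sqrt(a^2 + b^2),
                 phase = atan2(b, a), offset = best$coef[3],
                 fit_score = best$score, used_truncated = use_trunc,
                 failed = FALSE, reason = NULL),
            class = "sine_fit")
}

#' Dominant-harmonic frequency by FFT
#'
#' Discrete Fourier transform of the mean-subtracted combined signal; the
#' frequency of the non-DC bin with the largest magnitude is returned (the
#' first harmonic of the beat). Resolution is `frame_rate / n_samples`,
#' i.e. one bin per `1/duration`.
#'
#' @param trace a `chamber_trace` (needs >= 8 samples).
#' @param frame_rate frames per second.
#' @return Frequency in 1/s, or `NA_real_` when no non-DC power exists.
#' @export
fft_frequency <- function(trace, frame_rate) {
  y <- trace$combined_signal
  n <- length(y)
  if (n < 8)
    cb_stop("cb_precondition_error", "FFT needs >= 8 samples, got %d", n)
  y <- y - mean(y)
  mag <- Mod(stats::fft(y))[2:(n %/% 2 + 1)]
  if (all(mag < 1e-10)) return(NA_real_)
  unname(which.max(mag)) * frame_rate / n
}

#' Autocorrelation quality score
#'
#' Maximum over lags from 2 samples to half the trace of the normalized
#' autocorrelation of the mean-subtracted combined signal. Each lag is
#' normalized by the energies of its two overlapping windows (a
#' Pearson-style normalization), so a perfect periodic signal scores ~1
#' regardless of how many cycles the overlap spans. A constant signal
#' scores 0 by convention.
#'
#' @param trace a `chamber_trace` (needs >= 12 samples).
#' @return Score in `[-1, 1]`.
#' @export
autocorrelation_score <- function(trace) {
  y <- trace$combined_signal
  n <- length(y)
  if (n < 12)
    cb_stop("cb_precondition_error", "autocorrelation needs >= 12 samples, got %d", n)
  y <- y - mean(y)
  if (sum(y^2) < 1e-20) return(0)
  lags <- 2:(n %/% 2)
  max(vapply(lags, function(k) {
    a <- y[1:(n - k)]; b <- y[(k + 1):n]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den < 1e-20) 0 else sum(a * b) / den
  }, numeric(1)))
}

#' Full frequency characterization of one chamber trace
#'
#' Convenience wrapper assembling the sine fit, the FFT first-harmonic
#' frequency and the autocorrelation score into one record.
#'
#' @inheritParams fit_sine
#' @param ... passed to [fit_sine()].
#' @return A `frequency_fit` list: all `sine_fit` fields plus `fft_freq`
#'   and `autocorr_score`.
#' @export
estimate_frequency <- function(trace, frame_rate, ...) {
  sf <- fit_sine(trace, frame_rate, ...)
  sf$fft_freq <- if (isTRUE(trace$constant)) NA_real_ else fft_frequency(trace, frame_rate)
  sf$autocorr_score <- autocorrelation_score(trace)
  class(sf) <- c("frequency_fit", "sine_fit")
  sf
}
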