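#' Select the most motile pixels of a brightfield recording
#'
#' Computes the temporal standard deviation of every pixel over all frames
#' and selects the 10 highest-SD pixels (the beating heart region moves
#' most); ties are broken in row-major pixel order. Their mean time series
#' is the automated brightfield heartbeat trace.
#'
#' @param stack a [frame_stack()] with >= 2 frames.
#' @return A `pixel_trace_set`: `coords` (row/col matrix), `sd`, `traces`
#'   (pixels x frames), `averaged` trace.
#' @export
bf_select_pixels <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (n < 2) cb_stop("cb_precondition_error", "need >= 2 frames")
  s1 <- Reduce(`+`, stack$frames)
  s2 <- Reduce(`+`, lapply(stack$frames, function(m) m * m))
  sdmat <- sqrt(pmax((s2 - s1^2 / n) / (n - 1), 0))
  if (max(sdmat) <= 1e-12)
    cb_stop("cb_no_motion_error", "no motion detected: all pixels constant")
  d <- dim(sdmat)
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  rm_order <- (rows - 1) * d[2] + cols           # row-major tie-break
  cand <- which(as.vector(sdmat) > 0)
  ord <- cand[order(-sdmat[cand], rm_order[cand])]
  sel <- ord[seq_len(min(10L, length(ord)))]
  traces <- vapply(stack$frames, function(m) m[sel], numeric(length(sel)))
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  structure(list(coords = cbind(row = rows[sel], col = cols[sel]),
                 sd = sdmat[sel], traces = traces,
                 averaged = colMeans(traces)),
            class = "pixel_trace_set")
}

#' Fully automated brightfield heart rate
#'
#' Averages the 10 highest-variance pixel traces, detrends and normalizes
#' the result, and estimates the beat frequency by sine fitting and by the
#' FFT first harmonic. The reported heart rate uses the FFT estimate below
#' 9 f/s and the sine estimate otherwise.
#'
#' @param stack a [frame_stack()].
#' @param ... passed to [fit_sine()].
#' @return List: `freq` (sine, 1/s), `fft_freq` (1/s), `hr_bpm`, `route`
#'   (`"sine"` or `"fft"`), `fit` (the full `frequency_fit`).
#' @export
bf_heart_rate <- function(stack, ...) {
  sel <- bf_select_pixels(stack)
  tr <- trace_from_signal(sel$averaged, stack$frame_rate)
  fit <- estimate_frequency(tr, stack$frame_rate, ...)
  route <- if (stack$frame_rate < 9) "fft" else "sine"
  f <- if (route == "fft") fit$fft_freq else fit$freq
  if (!is.finite(f)) {
    # fall back to the other estimator before giving up
    alt <- if (route == "fft") fit$freq else fit$fft_freq
    if (is.finite(alt)) { f <- alt; route <- setdiff(c("sine", "fft"), route) }
    else cb_stop("cb_fit_failure_error", "no usable frequency estimate")
  }
  list(freq = fit$freq, fft_freq = fit$fft_freq, hr_bpm = 60 * f,
       route = route, fit = fit)
}
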