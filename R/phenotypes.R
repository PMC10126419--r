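#' Heart size from early frames
#'
#' Total heart area (atrium + ventricle) per frame, summarized as the
#' median over the first six frames, which keeps the morphology estimate
#' independent of beat phase coverage later in the recording.
#'
#' @param masks a `chamber_mask_series` with at least 6 frames.
#' @return Heart size in square micrometres.
#' @export
heart_size <- function(masks) {
  areas <- chamber_area_series(masks)
  total <- areas$atrium + areas$ventricle
  if (length(total) < 6)
    cb_stop("cb_precondition_error", "heart size needs >= 6 frames, got %d",
            length(total))
  stats::median(total[1:6])
}

#' Dilation and contraction extremes of a chamber
#'
#' Robust extremes of the per-frame area trace: the 95th percentile as
#' maximal dilation and the 5th percentile as maximal contraction, so a
#' single glitched segmentation frame cannot dominate contractility.
#'
#' @param area_trace numeric vector of per-frame chamber areas (µm²).
#' @return Named numeric vector `c(max_dilation, max_contraction)` in µm².
#' @export
chamber_extremes <- function(area_trace) {
  if (length(area_trace) == 0)
    cb_stop("cb_precondition_error", "empty area trace")
  q <- stats::quantile(area_trace, c(0.95, 0.05), names = FALSE)
  c(max_dilation = q[1], max_contraction = q[2])
}

#' Chamber contractility
#'
#' Absolute contractility is the area of the maximally dilated chamber
#' minus the area of the maximally contracted chamber; relative
#' contractility divides that difference by the dilated area, in percent.
#'
#' @param max_dilation,max_contraction chamber areas in µm² with
#'   `max_dilation >= max_contraction >= 0` and `max_dilation > 0`.
#' @return List with `absolute` (µm²) and `relative` (%).
#' @export
contractility <- function(max_dilation, max_contraction) {
  if (max_dilation <= 0)
    cb_stop("cb_undefined_result_error", "max_dilation must be > 0")
  if (max_contraction < 0 || max_contraction > max_dilation)
    cb_stop("cb_precondition_error",
            "need max_dilation >= max_contraction >= 0")
  absolute <- max_dilation - max_contraction
  list(absolute = absolute, relative = 100 * absolute / max_dilation)
}

#' Approximate ejection fraction from chamber areas
#'
#' Projected 2-D areas are converted to approximate volumes by the
#' isotropic scaling `V ~ A^(3/2)`; the ejection fraction is the
#' fractional volume change per beat,
#' `EF = 100 (1 - (A_contraction / A_dilation)^exponent)`.
#'
#' @inheritParams contractility
#' @param exponent area-to-volume exponent (default 3/2).
#' @return Ejection fraction in percent.
#' @export
ejection_fraction <- function(max_dilation, max_contraction, exponent = 1.5) {
  if (max_dilation <= 0)
    cb_stop("cb_undefined_result_error", "max_dilation must be > 0")
  if (max_contraction < 0 || max_contraction > max_dilation)
    cb_stop("cb_precondition_error",
            "need max_dilation >= max_contraction >= 0")
  100 * (1 - (max_contraction / max_dilation)^exponent)
}

# detect beat peaks in a normalized combined signal
detect_beats <- function(trace, frame_rate, freq = NA_real_) {
  y <- trace$combined_signal
  mid <- (min(y) + max(y)) / 2
  minsep <- if (is.finite(freq) && freq > 0)
    max(1L, round(0.5 / freq * frame_rate)) else 2L
  pk <- pracma::findpeaks(y, minpeakheight = mid, minpeakdistance = minsep)
  if (is.null(pk)) integer(0) else sort(pk[, 2])
}

#' Arrhythmia score of one chamber
#'
#' Beats are the peaks of the combined signal above mid-range with a
#' minimum separation of half a beat period. The score is the coefficient
#' of variation of inter-beat intervals (population SD over mean) scaled so
#' that a CV of 0.5 maps to 1: `score = min(1, CV / 0.5)`. 0 means
#' metronomic; scores >= 0.7 are flagged arrhythmic. Fewer than 3 detected
#' beats give an indeterminate result.
#'
#' @param trace a `chamber_trace`.
#' @param fit optional `sine_fit`/`frequency_fit` providing the beat
#'   frequency used for the peak-separation floor.
#' @param frame_rate frames per second.
#' @return List: `score` in `[0, 1]` (or `NA`), `n_beats`, `flagged`,
#'   `indeterminate`.
#' @export
arrhythmia_score <- function(trace, fit = NULL, frame_rate) {
  freq <- if (!is.null(fit) && !isTRUE(fit$failed)) fit$freq else NA_real_
  peaks <- detect_beats(trace, frame_rate, freq)
  if (length(peaks) < 3)
    return(list(score = NA_real_, n_beats = length(peaks),
                flagged = NA, indeterminate = TRUE))
  intervals <- diff(peaks) / frame_rate
  cv <- pop_sd(intervals) / mean(intervals)
  score <- min(1, cv / 0.5)
  list(score = score, n_beats = length(peaks),
       flagged = score >= 0.7, indeterminate = FALSE)
}

# simple atrium:ventricle ratios the beat ratio may snap to
.conduction_ratios <- list(c(1L, 1L), c(2L, 1L), c(3L, 1L), c(3L, 2L),
                           c(4L, 1L), c(1L, 2L), c(2L, 3L), c(1L, 3L), c(1L, 4L))

#' Atrioventricular conduction score and beat ratio
#'
#' Compares the beat frequencies of the two chambers. The atrium:ventricle
#' ratio is snapped to the nearest simple ratio (1:1, 2:1, 3:1, 3:2, 4:1
#' or their inverses) within a relative tolerance; when snapping succeeds
#' the score is the frequency mismatch of the snapped ratio,
#' `1 - min(a, b) / max(a, b)` (so a 2:1 block scores exactly 0.5 and 1:1
#' scores 0), otherwise the raw mismatch
#' `|f_a - f_v| / max(f_a, f_v)` is used and the ratio is reported
#' `"irregular"`. Scores >= 0.5 are flagged as a conduction defect; a
#' flagged 2:1 ratio is annotated as a Mobitz-II-like block. At frame
#' rates below 9 f/s the FFT frequency estimate is used, otherwise the
#' sine-fit estimate.
#'
#' @param fit_a,fit_v `frequency_fit`s for atrium and ventricle.
#' @param frame_rate frames per second.
#' @param snap_tol relative tolerance for ratio snapping (default 0.15).
#' @return List: `score`, `beat_ratio` (text), `ratio_raw`, `flagged`,
#'   `annotation` (or `NA`). A missing chamber frequency yields `score =
#'   NA` and `flagged = NA`.
#' @export
conduction_score <- function(fit_a, fit_v, frame_rate, snap_tol = 0.15) {
  pick <- function(fit) {
    if (is.null(fit)) return(NA_real_)
    f <- if (frame_rate < 9) fit$fft_freq else fit$freq
    if (is.null(f) || !is.finite(f) || f <= 0) NA_real_ else f
  }
  fa <- pick(fit_a); fv <- pick(fit_v)
  if (!is.finite(fa) || !is.finite(fv))
    return(list(score = NA_real_, beat_ratio = NA_character_,
                ratio_raw = NA_real_, flagged = NA, annotation = NA_character_))
  r <- fa / fv
  snapped <- NULL
  for (cand in .conduction_ratios) {
    v <- cand[1] / cand[2]
    if (abs(r - v) <= snap_tol * v) { snapped <- cand; break }
  }
  if (!is.null(snapped)) {
    score <- 1 - min(snapped) / max(snapped)
    ratio <- sprintf("%d:%d", snapped[1], snapped[2])
  } else {
    score <- 1 - min(fa, fv) / max(fa, fv)
    ratio <- "irregular"
  }
  flagged <- score >= 0.5
  annotation <- if (flagged && identical(ratio, "2:1"))
    "2:1 block (Mobitz-II-like)" else NA_character_
  list(score = score, beat_ratio = ratio, ratio_raw = r,
       flagged = flagged, annotation = annotation)
}
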