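#' Analyze one fluorescence heartbeat recording
#'
#' Runs the full chamber-specific workflow on a frame stack: heart ROI
#' detection, per-frame chamber segmentation from seed polygons, heartbeat
#' trace extraction, sine and FFT frequency estimation, and all phenotype
#' scores, assembled into a [phenotype_record()].
#'
#' @param stack a [frame_stack()].
#' @param seeds a [chamber_seeds()] in (rotated) ROI coordinates.
#' @param roi optional [heart_roi()]; detected automatically when `NULL`.
#' @param primary_threshold_quantile,roi_pad passed to [detect_heart_roi()]
#'   when the ROI is detected here.
#' @param secondary_threshold_frac passed to [segment_chambers()].
#' @param ... passed to [fit_sine()] via [estimate_frequency()].
#' @return List: `record` (a [phenotype_record()]), `traces`, `fits`,
#'   `masks`, `roi`.
#' @export
analyze_heart <- function(stack, seeds, roi = NULL,
                          primary_threshold_quantile = 0.90, roi_pad = 8L,
                          secondary_threshold_frac = 0.60, ...) {
  if (is.null(roi))
    roi <- detect_heart_roi(stack, primary_threshold_quantile, pad = roi_pad)
  masks <- segment_chambers(stack, roi, seeds, secondary_threshold_frac)
  fr <- stack$frame_rate
  traces <- list(); fits <- list()
  rec_args <- list(source_id = stack$source_id)
  for (ch in c("atrium", "ventricle")) {
    tr <- extract_heartbeat_trace(stack, masks, ch)
    ft <- estimate_frequency(tr, fr, ...)
    traces[[ch]] <- tr
    fits[[ch]] <- ft
    areas <- chamber_area_series(masks)[[ch]]
    ext <- chamber_extremes(areas)
    dil <- unname(ext["max_dilation"]); ctr <- unname(ext["max_contraction"])
    con <- contractility(dil, ctr)
    ef <- ejection_fraction(dil, ctr)
    arr <- arrhythmia_score(tr, ft, fr)
    pre <- function(x) stats::setNames(x, paste0(ch, "_", names(x)))
    rec_args <- c(rec_args, pre(list(
      freq_hz = if (ft$failed) NA_real_ else ft$freq,
      fft_freq_hz = ft$fft_freq,
      fit_score = ft$fit_score,
      autocorr_score = ft$autocorr_score,
      used_truncated = ft$used_truncated,
      max_dilation_um2 = dil,
      max_contraction_um2 = ctr,
      abs_contractility_um2 = con$absolute,
      rel_contractility_pct = con$relative,
      ejection_fraction_pct = ef,
      arrhythmia_score = arr$score,
      arrhythmic = arr$flagged
    )))
    rec_args[[paste0("hr_", ch, "_bpm")]] <-
      if (ft$failed) NA_real_ else 60 * ft$freq
    rec_args[[paste0("hr_", ch, "_fft_bpm")]] <-
      if (is.finite(ft$fft_freq)) 60 * ft$fft_freq else NA_real_
  }
  rec_args$heart_size_um2 <- heart_size(masks)
  cs <- conduction_score(fits$atrium, fits$ventricle, fr)
  rec_args$conduction_score <- cs$score
  rec_args$beat_ratio <- cs$beat_ratio
  rec_args$conduction_defect <- cs$flagged
  if (!is.na(cs$annotation)) rec_args$notes <- cs$annotation
  record <- do.call(phenotype_record, rec_args)
  list(record = record, traces = traces, fits = fits, masks = masks, roi = roi)
}
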