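#' Per-fish phenotype record
#'
#' The full output row for one analyzed fish. Any field can be left `NA`
#' (e.g. after a failed ventricle fit); [write_results_sheet()] writes `NA`
#' fields as empty cells.
#'
#' @param source_id recording label.
#' @param ... named phenotype fields; see Details for the column set.
#' @details Columns, per chamber where applicable: sine (`*_freq_hz`) and
#' FFT (`*_fft_freq_hz`) frequencies with derived heart rates in beats/min,
#' fitting and autocorrelation quality scores, heart size (µm², median of
#' the first six frames), dilation/contraction extremes (µm²), absolute
#' (µm²) and relative (%) contractility, approximate ejection fraction (%),
#' arrhythmia score with flag, conduction score with atrium:ventricle beat
#' ratio and flag, and free-text notes.
#' @return A list of class `phenotype_record` with the fixed column set.
#' @export
phenotype_record <- function(source_id, ...) {
  fields <- c(
    "atrium_freq_hz", "atrium_fft_freq_hz", "hr_atrium_bpm", "hr_atrium_fft_bpm",
    "atrium_fit_score", "atrium_autocorr_score", "atrium_used_truncated",
    "ventricle_freq_hz", "ventricle_fft_freq_hz", "hr_ventricle_bpm",
    "hr_ventricle_fft_bpm", "ventricle_fit_score", "ventricle_autocorr_score",
    "ventricle_used_truncated",
    "heart_size_um2",
    "atrium_max_dilation_um2", "atrium_max_contraction_um2",
    "atrium_abs_contractility_um2", "atrium_rel_contractility_pct",
    "atrium_ejection_fraction_pct", "atrium_arrhythmia_score", "atrium_arrhythmic",
    "ventricle_max_dilation_um2", "ventricle_max_contraction_um2",
    "ventricle_abs_contractility_um2", "ventricle_rel_contractility_pct",
    "ventricle_ejection_fraction_pct", "ventricle_arrhythmia_score",
    "ventricle_arrhythmic",
    "conduction_score", "beat_ratio", "conduction_defect", "notes"
  )
  rec <- stats::setNames(as.list(rep(NA, length(fields))), fields)
  rec$source_id <- source_id
  dots <- list(...)
  bad <- setdiff(names(dots), fields)
  if (length(bad) > 0)
    cb_stop("cb_format_error", "unknown phenotype fields: %s",
            paste(bad, collapse = ", "))
  rec[names(dots)] <- dots
  structure(rec[c("source_id", fields)], class = "phenotype_record")
}

#' Write the results data sheet
#'
#' One comma-separated row per fish (UTF-8, `.` decimal separator), header
#' row first, missing values as empty cells.
#'
#' @param records non-empty list of [phenotype_record()]s.
#' @param path output CSV path.
#' @export
write_results_sheet <- function(records, path) {
  if (length(records) == 0)
    cb_stop("cb_format_error", "no records to write")
  if (inherits(records, "phenotype_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "phenotype_record"))
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cb_stop("cb_io_error", "cannot write results sheet to %s", path)
  invisible(path)
}

# blue -> yellow lookup table plus overlay colors:
# 0..251 intensity ramp, 252 white (atrium outline), 253 red (ventricle)
heartbeat_palette <- function() {
  ramp <- grDevices::colorRamp(c("#0000FF", "#FFFF00"))(seq(0, 1, length.out = 252))
  pal <- matrix(0L, 256, 3)
  pal[1:252, ] <- round(ramp)
  pal[253, ] <- c(255L, 255L, 255L)
  pal[254, ] <- c(255L, 0L, 0L)
  pal
}

mask_outline <- function(m) {
  up    <- rbind(m[-1, , drop = FALSE], FALSE)
  down  <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
  left  <- cbind(m[, -1, drop = FALSE], FALSE)
  right <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
  m & !(up & down & left & right)
}

#' Render the heartbeat animation
#'
#' Writes an animated GIF of the recording with intensities mapped through a
#' blue (stack-wide minimum) to yellow (stack-wide maximum) lookup table and
#' the segmented chamber outlines overlaid on every frame (atrium white,
#' ventricle red).
#'
#' @param stack a [frame_stack()].
#' @param masks a `chamber_mask_series` aligned frame-for-frame with `stack`.
#' @param path output `.gif` path.
#' @export
render_heartbeat_animation <- function(stack, masks, path) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (length(masks$atrium) != n || length(masks$ventricle) != n)
    cb_stop("cb_alignment_error",
            "mask series length (%d/%d) does not match stack length (%d)",
            length(masks$atrium), length(masks$ventricle), n)
  lo <- min(vapply(stack$frames, min, numeric(1)))
  hi <- max(vapply(stack$frames, max, numeric(1)))
  flat <- (hi - lo) <= 0
  frames_idx <- vector("list", n)
  for (i in seq_len(n)) {
    f <- stack$frames[[i]]
    idx <- if (flat) matrix(126L, nrow(f), ncol(f))
           else matrix(as.integer(round((f - lo) / (hi - lo) * 251)), nrow(f))
    idx[mask_outline(masks$atrium[[i]])] <- 252L
    idx[mask_outline(masks$ventricle[[i]])] <- 253L
    frames_idx[[i]] <- idx
  }
  delay <- max(2L, as.integer(round(100 / stack$frame_rate)))
  gif_write(frames_idx, heartbeat_palette(), path, delay_cs = delay)
  invisible(path)
}

#' Render the two-panel heartbeat trace plot
#'
#' One panel per chamber: the raw combined heartbeat signal with the fitted
#' sine overlaid as a red dotted line; the panel title reports the sine and
#' FFT frequency estimates. A chamber whose fit failed (or is `NULL`) gets a
#' raw-only panel.
#'
#' @param traces named list with `atrium` and `ventricle` `chamber_trace`s.
#' @param fits named list with the matching `frequency_fit`s (entries may be
#'   `NULL` or failed fits).
#' @param path output `.png` path.
#' @export
render_trace_plot <- function(traces, fits, path) {
  for (ch in c("atrium", "ventricle"))
    if (is.null(traces[[ch]]) || length(traces[[ch]]$time) == 0)
      cb_stop("cb_format_error", "zero-length trace for %s", ch)
  grDevices::png(path, width = 900, height = 600, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 3, 1))
  for (ch in c("atrium", "ventricle")) {
    tr <- traces[[ch]]; ft <- fits[[ch]]
    graphics::plot(tr$time, tr$combined_signal, type = "l", col = "black",
                   xlab = "time [s]", ylab = "normalized signal",
                   ylim = c(-0.05, 1.05))
    ok <- !is.null(ft) && !isTRUE(ft$failed) && is.finite(ft$freq)
    if (ok) {
      tt <- seq(min(tr$time), max(tr$time), length.out = 400)
      yy <- ft$amplitude * sin(2 * pi * ft$freq * tt + ft$phase) + ft$offset
      graphics::lines(tt, yy, col = "red", lty = 3, lwd = 2)
      ttl <- sprintf("%s: freq = %.3f 1/s, fft_freq = %.3f 1/s, fit score = %.3f",
                     ch, ft$freq, ifelse(is.finite(ft$fft_freq), ft$fft_freq, NA),
                     ft$fit_score)
    } else ttl <- sprintf("%s: no valid sine fit", ch)
    graphics::title(ttl)
  }
  invisible(path)
}
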