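#' Ordered grayscale frame stack
#'
#' The raw input of every analysis: a list of 2-D intensity matrices sharing
#' one size, together with the acquisition frame rate (frames/second) and
#' pixel size (micrometres/pixel). Intensities are kept at native depth
#' (e.g. 0--255 for 8-bit, 0--65535 for 16-bit input).
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param frame_rate frames per second, > 0.
#' @param pixel_size micrometres per pixel, > 0.
#' @param source_id text label identifying the recording.
#' @return An object of class `frame_stack` with fields `frames`,
#'   `frame_rate`, `pixel_size` and `source_id`.
#' @export
frame_stack <- function(frames, frame_rate, pixel_size, source_id = "stack") {
  if (!is.list(frames) || length(frames) == 0)
    cb_stop("cb_format_error", "frames must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    cb_stop("cb_format_error", "all frames must share identical dimensions")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    cb_stop("cb_format_error", "frame_rate must be > 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    cb_stop("cb_format_error", "pixel_size must be > 0")
  structure(
    list(frames = frames, frame_rate = frame_rate, pixel_size = pixel_size,
         source_id = source_id),
    class = "frame_stack"
  )
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Recording duration in seconds
#' @param stack a [frame_stack()].
#' @return `n_frames / frame_rate`, in seconds.
#' @export
stack_duration <- function(stack) length(stack$frames) / stack$frame_rate

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack '%s': %d frames %dx%d, %.3g f/s, %.3g um/px, %.3g s>\n",
              x$source_id, length(x$frames), d[1], d[2],
              x$frame_rate, x$pixel_size, stack_duration(x)))
  invisible(x)
}

#' Acquisition configuration
#'
#' Frame skipping and trimming applied while loading a recording. Keeping
#' every `skip_interval`-th frame divides the effective frame rate; trimming
#' keeps at most `trim_seconds` of recording measured from the start.
#'
#' @param frame_rate acquisition frame rate of the source, frames/second.
#' @param pixel_size micrometres per pixel.
#' @param skip_interval integer >= 1; keep every k-th frame.
#' @param trim_seconds optional positive duration cap in seconds.
#' @param overwrite logical; downstream writers may replace existing output.
#' @return A list of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate, pixel_size, skip_interval = 1L,
                               trim_seconds = NULL, overwrite = FALSE) {
  skip_interval <- as.integer(skip_interval)
  if (is.na(skip_interval) || skip_interval < 1L)
    cb_stop("cb_format_error", "skip_interval must be an integer >= 1")
  if (!is.null(trim_seconds) && (!is.numeric(trim_seconds) || trim_seconds <= 0))
    cb_stop("cb_format_error", "trim_seconds must be a positive duration")
  structure(list(frame_rate = frame_rate, pixel_size = pixel_size,
                 skip_interval = skip_interval, trim_seconds = trim_seconds,
                 overwrite = isTRUE(overwrite)),
            class = "acquisition_config")
}

# Rec. 601 luminance for color input
luminance <- function(arr) {
  if (length(dim(arr)) == 2) return(arr)
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE, all = TRUE),
    png = png::readPNG(path) * 255,
    cb_stop("cb_format_error", "unsupported frame format '%s': %s", ext, path)
  ), error = function(e) {
    if (inherits(e, "cb_error")) stop(e)
    cb_stop("cb_format_error", "unreadable frame file %s (%s)",
            path, conditionMessage(e))
  })
  # frames are held as double matrices at native sample values
  if (!is.list(img)) img <- list(img)
  lapply(img, function(x) luminance(x) + 0)
}

#' Load a recording into a frame stack
#'
#' Reads a TIFF/PNG image series (a directory of one file per frame, ordered
#' by the numeric part of filenames) or a multi-page TIFF into a
#' [frame_stack()], applying the frame skipping and start-anchored trimming
#' of the [acquisition_config()]. Color frames are converted to luminance by
#' Rec. 601 weights. Video containers (AVI/MP4) are not supported; convert
#' them to an image series upstream.
#'
#' @param source path to a directory of frame files or to a (multi-page)
#'   TIFF/PNG file.
#' @param config an [acquisition_config()].
#' @return A [frame_stack()] whose `frame_rate` is the effective rate after
#'   skipping.
#' @export
load_frame_stack <- function(source, config) {
  stopifnot(inherits(config, "acquisition_config"))
  if (!file.exists(source))
    cb_stop("cb_format_error", "source does not exist: %s", source)
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("avi", "mp4", "mov", "czi"))
    cb_stop("cb_format_error",
            "video/proprietary container '%s' is not supported; supply a TIFF/PNG image series", ext)
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0)
      cb_stop("cb_format_error", "no TIFF/PNG frames found in %s", source)
    files <- files[natural_order(files)]
    frames <- list()
    for (f in files) {
      fr <- read_frame_file(f)
      if (length(frames) > 0 && !identical(dim(fr[[1]]), dim(frames[[1]])))
        cb_stop("cb_format_error", "frame size mismatch at %s", f)
      frames <- c(frames, fr)
    }
    src_id <- basename(source)
  } else {
    frames <- read_frame_file(source)
    src_id <- tools::file_path_sans_ext(basename(source))
  }
  keep <- seq(1, length(frames), by = config$skip_interval)
  frames <- frames[keep]
  eff_rate <- config$frame_rate / config$skip_interval
  if (!is.null(config$trim_seconds)) {
    n_keep <- min(length(frames), floor(config$trim_seconds * eff_rate))
    frames <- frames[seq_len(n_keep)]
  }
  if (length(frames) < 6)
    cb_stop("cb_insufficient_data_error",
            "fewer than 6 frames after skipping/trimming (%d); morphology needs six",
            length(frames))
  frame_stack(frames, eff_rate, config$pixel_size, src_id)
}

#' Write a frame stack as a TIFF image series
#'
#' One `frame_0001.tif`-style file per frame at the requested bit depth.
#' Inverse of loading a directory with [load_frame_stack()].
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if needed).
#' @param bits bits per sample, 8 or 16; intensities are assumed to lie in
#'   `[0, 2^bits - 1]`.
#' @return Invisibly, the written file paths.
#' @export
write_frame_stack <- function(stack, dir, bits = 16L) {
  stopifnot(inherits(stack, "frame_stack"), bits %in% c(8L, 16L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- 2^bits - 1
  paths <- character(length(stack$frames))
  for (i in seq_along(stack$frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%04d.tif", i))
    m <- pmin(pmax(stack$frames[[i]], 0), top) / top
    tiff::writeTIFF(m, paths[i], bits.per.sample = bits)
  }
  invisible(paths)
}
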