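#' Heart region of interest
#'
#' Bounding box in frame coordinates (1-based inclusive rows/cols) plus a
#' rotation angle in degrees applied about the box center before chamber
#' seeds are interpreted.
#'
#' @param rows,cols integer length-2 vectors, first/last row and column.
#' @param rotation_angle degrees, counter-clockwise.
#' @export
heart_roi <- function(rows, cols, rotation_angle = 0) {
  if (rows[1] > rows[2] || cols[1] > cols[2])
    cb_stop("cb_format_error", "empty ROI box")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 rotation_angle = rotation_angle), class = "heart_roi")
}

#' Chamber seed polygons
#'
#' User-supplied polygons marking which blob is the atrium and which the
#' ventricle, in (rotated) ROI pixel coordinates. Chamber identity is taken
#' from the argument names, never inferred from geometry.
#'
#' @param atrium,ventricle two-column matrices of polygon vertices
#'   `(x = col, y = row)`, 1-based ROI coordinates.
#' @export
chamber_seeds <- function(atrium, ventricle) {
  for (p in list(atrium, ventricle)) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      cb_stop("cb_format_error", "seed polygons need >= 3 (x, y) vertices")
    if (abs(polygon_area(p)) <= 0)
      cb_stop("cb_format_error", "degenerate seed polygon (zero area)")
  }
  structure(list(atrium = atrium, ventricle = ventricle),
            class = "chamber_seeds")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# rasterize a polygon onto an nr x nc pixel grid (pixel centers at integers)
poly_mask <- function(p, nr, nc) {
  bnd <- rbind(p, p[1, ])
  pts <- cbind(rep(seq_len(nc), each = nr), rep(seq_len(nr), nc))  # (x, y)
  inside <- mgcv::in.out(bnd, pts)
  matrix(inside, nrow = nr, ncol = nc)
}

# exact rotation for multiples of 90 degrees, bilinear otherwise
rotate_frame <- function(m, angle) {
  a <- ((angle %% 360) + 360) %% 360
  if (a == 0) return(m)
  if (a %in% c(90, 180, 270)) {
    out <- m
    # one CCW quarter turn: transpose then reverse rows
    for (k in seq_len(a / 90)) out <- t(out)[ncol(out):1, , drop = FALSE]
    return(out)
  }
  as.matrix(EBImage::rotate(EBImage::as.Image(m), a, output.dim = dim(m),
                            bg.col = 0))
}

#' Detect the heart region of interest
#'
#' Thresholds the temporal-maximum image at an intensity quantile and takes
#' the bounding box of the largest connected supra-threshold component,
#' padded by `pad` pixels and clipped to the frame. A dim atrioventricular
#' canal above the threshold keeps the two chambers in one component, so the
#' ROI covers the whole heart.
#'
#' @param stack a [frame_stack()].
#' @param primary_threshold_quantile quantile of the temporal-maximum
#'   image's intensities used as the detection threshold (default 0.90).
#' @param pad margin in pixels around the detected component.
#' @return A [heart_roi()] with `rotation_angle = 0`.
#' @export
detect_heart_roi <- function(stack, primary_threshold_quantile = 0.90, pad = 8L) {
  stopifnot(inherits(stack, "frame_stack"))
  maximg <- Reduce(pmax, stack$frames)
  thr <- stats::quantile(maximg, primary_threshold_quantile, names = FALSE)
  bw <- maximg > thr
  if (!any(bw)) cb_stop("cb_no_heart_error", "no heart detected: no pixels above threshold")
  lab <- EBImage::bwlabel(bw)
  counts <- tabulate(lab[lab > 0])
  if (length(counts) == 0) cb_stop("cb_no_heart_error", "no heart detected")
  best <- which.max(counts)
  px <- which(lab == best, arr.ind = TRUE)
  d <- dim(maximg)
  heart_roi(
    rows = c(max(1L, min(px[, 1]) - pad), min(d[1], max(px[, 1]) + pad)),
    cols = c(max(1L, min(px[, 2]) - pad), min(d[2], max(px[, 2]) + pad))
  )
}

roi_crop <- function(frame, roi) {
  frame[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], drop = FALSE]
}

#' Segment atrium and ventricle in every frame
#'
#' Within the (optionally rotated) ROI of each frame a secondary intensity
#' threshold is placed at a fixed fraction of that frame's within-ROI
#' intensity range (robustified by 0.1th/99.9th percentiles, so single hot
#' pixels cannot move it); pixels above it are labeled into connected
#' components and each chamber is the component that maximally overlaps its
#' seed polygon. The atrioventricular canal, dimmer than the chambers,
#' falls below the threshold and so separates the two components. If both
#' seeds select the same component it is split by distance to the seed
#' centroids (with a warning). Masks are reported on the full frame canvas
#' and are disjoint in every frame.
#'
#' The threshold is anchored to the intensity range rather than to an
#' intensity quantile because the fraction of the ROI occupied by
#' background changes with the beat phase, which would move a
#' fixed-quantile threshold across the canal/chamber gap during the cycle.
#'
#' @param stack a [frame_stack()].
#' @param roi a [heart_roi()]; seeds live in its (rotated) coordinates.
#' @param seeds a [chamber_seeds()].
#' @param secondary_threshold_frac per-frame threshold as a fraction in
#'   (0, 1) of the within-ROI intensity range (default 0.60; must exceed
#'   the canal-to-chamber intensity ratio).
#' @param smooth_radius half-width in pixels of the box filter applied to
#'   the ROI before thresholding (default 1, i.e. 3x3; 0 disables).
#'   Suppresses pixel noise that would otherwise punch holes into the
#'   chamber components at low signal-to-noise ratios.
#' @return A `chamber_mask_series`: lists `atrium` and `ventricle` of
#'   per-frame logical matrices (frame-sized), plus `pixel_size`, `roi` and
#'   per-chamber counts of frames without a supra-threshold overlap.
#' @export
segment_chambers <- function(stack, roi, seeds,
                             secondary_threshold_frac = 0.60,
                             smooth_radius = 1L) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "heart_roi"),
            inherits(seeds, "chamber_seeds"))
  nr <- roi$rows[2] - roi$rows[1] + 1L
  nc <- roi$cols[2] - roi$cols[1] + 1L
  for (ch in c("atrium", "ventricle")) {
    p <- seeds[[ch]]
    if (any(p[, 1] < 1 | p[, 1] > nc | p[, 2] < 1 | p[, 2] > nr))
      cb_stop("cb_precondition_error", "%s seed polygon lies outside the ROI", ch)
  }
  seed_masks <- lapply(seeds[c("atrium", "ventricle")], poly_mask, nr = nr, nc = nc)
  cents <- lapply(seeds[c("atrium", "ventricle")], colMeans)  # (x, y)
  d <- dim(stack$frames[[1]])
  n <- length(stack$frames)
  out <- list(atrium = vector("list", n), ventricle = vector("list", n))
  misses <- c(atrium = 0L, ventricle = 0L)
  shared_warned <- FALSE
  # pixel coordinate grids in ROI space, for centroid-distance tie-breaking
  gx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  gy <- matrix(rep(seq_len(nr), nc), nr, nc)
  for (i in seq_len(n)) {
    sub <- roi_crop(stack$frames[[i]], roi)
    if (roi$rotation_angle != 0) sub <- rotate_frame(sub, roi$rotation_angle)
    if (smooth_radius > 0) {
      k <- 2L * as.integer(smooth_radius) + 1L
      sub <- as.matrix(EBImage::filter2(EBImage::as.Image(sub),
                                        matrix(1 / k^2, k, k),
                                        boundary = "replicate"))
    }
    rng <- stats::quantile(sub, c(0.001, 0.999), names = FALSE)
    thr <- rng[1] + secondary_threshold_frac * (rng[2] - rng[1])
    lab <- EBImage::bwlabel(sub > thr)
    pick <- vapply(c("atrium", "ventricle"), function(ch) {
      ov <- lab[seed_masks[[ch]]]
      ov <- ov[ov > 0]
      if (length(ov) == 0) 0L else as.integer(names(which.max(table(ov))))
    }, integer(1))
    masks <- list()
    if (pick[1] != 0L && pick[1] == pick[2]) {
      if (!shared_warned) {
        cb_warn("cb_shared_component_warning",
                "both seeds overlap one component; splitting by seed-centroid distance")
        shared_warned <- TRUE
      }
      comp <- lab == pick[1]
      da <- (gx - cents$atrium[1])^2 + (gy - cents$atrium[2])^2
      dv <- (gx - cents$ventricle[1])^2 + (gy - cents$ventricle[2])^2
      masks$atrium <- comp & (da <= dv)
      masks$ventricle <- comp & (da > dv)
    } else {
      masks$atrium <- if (pick[1] == 0L) matrix(FALSE, nr, nc) else lab == pick[1]
      masks$ventricle <- if (pick[2] == 0L) matrix(FALSE, nr, nc) else lab == pick[2]
    }
    for (ch in c("atrium", "ventricle")) {
      if (!any(masks[[ch]])) misses[ch] <- misses[ch] + 1L
      full <- matrix(FALSE, d[1], d[2])
      full[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]] <- masks[[ch]]
      out[[ch]][[i]] <- full
    }
  }
  for (ch in c("atrium", "ventricle"))
    if (misses[ch] > n / 2)
      cb_stop("cb_segmentation_error",
              "%s seed overlaps no supra-threshold component in %d of %d frames",
              ch, misses[ch], n)
  structure(list(atrium = out$atrium, ventricle = out$ventricle,
                 pixel_size = stack$pixel_size, roi = roi, misses = misses),
            class = "chamber_mask_series")
}

#' Per-chamber area traces
#'
#' @param masks a `chamber_mask_series`.
#' @return Named list of numeric vectors: per-frame chamber area in square
#'   micrometres (`pixel count * pixel_size^2`).
#' @export
chamber_area_series <- function(masks) {
  stopifnot(inherits(masks, "chamber_mask_series"))
  ps2 <- masks$pixel_size^2
  lapply(masks[c("atrium", "ventricle")],
         function(series) vapply(series, sum, numeric(1)) * ps2)
}
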