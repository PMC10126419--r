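#' Read the sidecar analysis config
#'
#' JSON file supplying acquisition metadata and chamber seeds. Required
#' keys: `frame_rate` (frames/second), `pixel_size` (µm/pixel) and `seeds`
#' with `atrium` and `ventricle` vertex lists, each an array of `[x, y]`
#' pixel coordinates in rotated-ROI space, 0-based (converted to the
#' package's 1-based convention on read). Optional keys: `skip_interval`,
#' `trim_seconds`, `primary_threshold_quantile`,
#' `secondary_threshold_frac`, `roi_pad`, `rotation_angle`,
#' `overwrite`.
#'
#' @param path path to the JSON config.
#' @param require_seeds whether missing seeds are an error (`FALSE` for the
#'   ROI-preview path used to author seed polygons).
#' @return A list of class `cb_config`.
#' @export
read_sidecar_config <- function(path, require_seeds = TRUE) {
  if (!file.exists(path))
    cb_stop("cb_usage_error", "config file not found: %s", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                  error = function(e)
                    cb_stop("cb_usage_error", "cannot parse config %s: %s",
                            path, conditionMessage(e)))
  missing <- setdiff(c("frame_rate", "pixel_size"), names(raw))
  if (!is.null(raw$seeds)) {
    if (is.null(raw$seeds$atrium)) missing <- c(missing, "seeds.atrium")
    if (is.null(raw$seeds$ventricle)) missing <- c(missing, "seeds.ventricle")
  } else if (require_seeds) missing <- c(missing, "seeds")
  if (length(missing) > 0)
    cb_stop("cb_usage_error", "config is missing required fields: %s",
            paste(missing, collapse = ", "))
  to_poly <- function(v) {
    m <- as.matrix(v)
    colnames(m) <- c("x", "y")
    m + 1  # 0-based JSON coordinates -> 1-based internal
  }
  cfg <- list(
    frame_rate = raw$frame_rate,
    pixel_size = raw$pixel_size,
    skip_interval = if (is.null(raw$skip_interval)) 1L else raw$skip_interval,
    trim_seconds = raw$trim_seconds,
    primary_threshold_quantile =
      if (is.null(raw$primary_threshold_quantile)) 0.90
      else raw$primary_threshold_quantile,
    secondary_threshold_frac =
      if (is.null(raw$secondary_threshold_frac)) 0.60
      else raw$secondary_threshold_frac,
    roi_pad = if (is.null(raw$roi_pad)) 8L else as.integer(raw$roi_pad),
    rotation_angle = if (is.null(raw$rotation_angle)) 0 else raw$rotation_angle,
    overwrite = isTRUE(raw$overwrite),
    seeds = if (is.null(raw$seeds)) NULL
            else chamber_seeds(atrium = to_poly(raw$seeds$atrium),
                               ventricle = to_poly(raw$seeds$ventricle))
  )
  structure(cfg, class = "cb_config")
}
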