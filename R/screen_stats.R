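#' Fold change relative to DMSO controls
#'
#' Divides every heart-rate value by the mean of the DMSO control rows of
#' the same experiment, which minimizes inter-experiment variation before
#' z-scoring.
#'
#' @param table data frame with columns `experiment_id`, `role`
#'   (`"control"` for DMSO rows, anything else for compounds) and `hr_bpm`.
#' @return `table` with a `fold_change` column appended.
#' @export
fold_change <- function(table) {
  need <- c("experiment_id", "role", "hr_bpm")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    cb_stop("cb_format_error", "missing columns: %s", paste(miss, collapse = ", "))
  table$fold_change <- NA_real_
  for (ex in unique(table$experiment_id)) {
    sel <- table$experiment_id == ex
    ctrl <- table$hr_bpm[sel & table$role == "control"]
    if (length(ctrl) == 0)
      cb_stop("cb_precondition_error", "experiment %s has no DMSO control rows", ex)
    m <- mean(ctrl)
    if (!is.finite(m) || m == 0)
      cb_stop("cb_precondition_error", "experiment %s has zero control mean", ex)
    table$fold_change[sel] <- table$hr_bpm[sel] / m
  }
  table
}

#' Z-score normalization
#'
#' Centers and scales by the sample (n-1 denominator) standard deviation
#' over all supplied fold-change values (one screen-wide population).
#'
#' @param fold_changes numeric vector, length >= 2 with non-zero spread.
#' @return Z-scores.
#' @export
zscore <- function(fold_changes) {
  if (length(fold_changes) < 2)
    cb_stop("cb_precondition_error", "z-scoring needs >= 2 values")
  s <- stats::sd(fold_changes)
  if (!is.finite(s) || s == 0)
    cb_stop("cb_precondition_error", "zero spread; z-scores undefined")
  (fold_changes - mean(fold_changes)) / s
}

#' Two-sided critical value for a confidence level
#'
#' Standard-normal critical value rounded to two decimals: 1.64 at the 90%
#' level, 1.96 at 95%.
#'
#' @param ci_level 90 or 95.
#' @return The threshold.
#' @export
ci_threshold <- function(ci_level) {
  if (!ci_level %in% c(90, 95))
    cb_stop("cb_format_error", "ci_level must be 90 or 95")
  round(stats::qnorm(1 - (1 - ci_level / 100) / 2), 2)
}

#' Flag screen hits by z-score
#'
#' @param z numeric z-scores.
#' @param ci_level confidence level, 90 (threshold 1.64, fewer false
#'   negatives) or 95 (1.96).
#' @return Logical vector: `|z| >=` threshold.
#' @export
flag_hits <- function(z, ci_level = 90) {
  abs(z) >= ci_threshold(ci_level)
}

#' Toxicity observation for one treatment group
#'
#' @param n_total embryos in the group (>= 1).
#' @param n_pericardial_edema,n_developmental_delay,n_cardiac_arrest
#'   affected counts, each in `[0, n_total]`.
#' @param hr_zscore z-score-normalized heart rate of the group.
#' @param deceased `TRUE` when the embryo is deceased and not intact.
#' @export
tox_observation <- function(n_total, n_pericardial_edema = 0,
                            n_developmental_delay = 0, n_cardiac_arrest = 0,
                            hr_zscore = 0, deceased = FALSE) {
  if (n_total < 1) cb_stop("cb_precondition_error", "n_total must be >= 1")
  counts <- c(n_pericardial_edema, n_developmental_delay, n_cardiac_arrest)
  if (any(counts < 0 | counts > n_total))
    cb_stop("cb_precondition_error", "counts must lie in [0, n_total]")
  structure(list(n_total = n_total, n_pericardial_edema = n_pericardial_edema,
                 n_developmental_delay = n_developmental_delay,
                 n_cardiac_arrest = n_cardiac_arrest, hr_zscore = hr_zscore,
                 deceased = isTRUE(deceased)),
            class = "tox_observation")
}

#' Composite toxicity score
#'
#' `ToxScore = edema/n + delay/n + 1(|z| >= 1.64) + 2 * arrest/n`, capped
#' at 5. An embryo recorded as deceased and not intact is assigned the
#' maximal score of 5 outright. The heart-rate term is an indicator for a
#' z-scored heart rate outside the 90% confidence band.
#'
#' @param obs a [tox_observation()].
#' @return Score in `[0, 5]`.
#' @export
tox_score <- function(obs) {
  stopifnot(inherits(obs, "tox_observation"))
  if (obs$deceased) return(5)
  n <- obs$n_total
  score <- obs$n_pericardial_edema / n +
    obs$n_developmental_delay / n +
    as.numeric(abs(obs$hr_zscore) >= ci_threshold(90)) +
    2 * obs$n_cardiac_arrest / n
  min(5, score)
}

#' Pearson validation correlation with 3-SD outlier exclusion
#'
#' Fits a least-squares line of `y` on `x`, excludes extreme outliers whose
#' residual exceeds three residual standard deviations, and reports the
#' Pearson correlation of the remaining points.
#'
#' @param x,y paired numeric vectors, >= 3 points.
#' @return List: `r`, `n_excluded`, `n_used`.
#' @export
validation_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    cb_stop("cb_precondition_error", "need >= 3 paired points")
  fit <- stats::lm(y ~ x)
  res <- stats::resid(fit)
  s <- stats::sd(res)
  keep <- abs(res) <= 3 * s + 1e-12 * max(1, abs(mean(y)))
  if (sum(keep) < 3)
    cb_stop("cb_precondition_error", "fewer than 3 points after outlier exclusion")
  list(r = stats::cor(x[keep], y[keep]), n_excluded = sum(!keep),
       n_used = sum(keep))
}
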