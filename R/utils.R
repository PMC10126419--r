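# internal helpers shared across modules

cb_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "cb_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

cb_warn <- function(class, fmt, ...) {
  warning(structure(
    class = c(class, "cb_warning", "warning", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# min-max normalization to [0, 1]; constant input maps to a flat 0.5
minmax_scale <- function(x) {
  r <- range(x)
  if (!is.finite(diff(r)) || diff(r) <= 0) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

# remove a least-squares linear trend, keeping the mean level
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  tt <- seq_len(n)
  unname(stats::resid(stats::lm(x ~ tt))) + mean(x)
}

# population (n-denominator) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# order filenames by the numeric part so frame_2 sorts before frame_10
natural_order <- function(paths) {
  base <- basename(paths)
  nums <- vapply(regmatches(base, gregexpr("[0-9]+", base)), function(m) {
    if (length(m) == 0) NA_real_ else as.numeric(m[length(m)])
  }, numeric(1))
  order(nums, base, na.last = TRUE)
}
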