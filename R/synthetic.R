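#' Parameters of the synthetic beating heart
#'
#' Defines the simulated study conditions: two pulsing bright chambers on a
#' dark background joined by a dimmer atrioventricular canal. Defaults
#' emulate a 2-dpf embryonic zebrafish heart imaged for a screen: 2.5 1/s
#' (150 beats/min) in both chambers, chamber areas around 10^4 µm²,
#' 40% area modulation, a 6-second recording at 30 frames/second and
#' 2.5 µm pixels.
#'
#' @param freq_atrium,freq_ventricle beat frequencies, 1/s.
#' @param phase_lag ventricular phase delay behind the atrium, radians.
#' @param atrium_area,ventricle_area maximally dilated chamber areas, µm².
#' @param contraction_atrium,contraction_ventricle fractional area
#'   modulation per beat in `[0, 1)` (0 = no contraction).
#' @param avc_intensity_fraction canal intensity as a fraction of chamber
#'   intensity, in (0, 1).
#' @param rhythm_mode `"regular"`, `"block_2to1"` (ventricle beats every
#'   second atrial beat), `"flutter"` (fast, low-amplitude atrium) or
#'   `"irregular"` (jittered inter-beat intervals).
#' @param irregular_jitter coefficient of variation of inter-beat
#'   intervals in irregular mode.
#' @param noise_sd additive Gaussian pixel noise SD, intensity units
#'   (chambers render at `intensity`).
#' @param frame_rate frames/second; `duration` seconds; `pixel_size`
#'   µm/pixel.
#' @param intensity chamber fluorescence intensity (8-bit-like scale).
#' @param width,height canvas size in pixels.
#' @param seed integer RNG seed; identical parameters and seed give a
#'   bit-identical stack.
#' @export
heart_sim_params <- function(freq_atrium = 2.5, freq_ventricle = 2.5,
                             phase_lag = pi / 4,
                             atrium_area = 8000, ventricle_area = 10000,
                             contraction_atrium = 0.4,
                             contraction_ventricle = 0.4,
                             avc_intensity_fraction = 0.45,
                             rhythm_mode = c("regular", "block_2to1",
                                             "flutter", "irregular"),
                             irregular_jitter = 0.2, noise_sd = 5,
                             frame_rate = 30, duration = 6, pixel_size = 2.5,
                             intensity = 150, width = 220L, height = 160L,
                             seed = 1L) {
  rhythm_mode <- match.arg(rhythm_mode)
  stopifnot(freq_atrium > 0, freq_ventricle > 0, frame_rate > 0, duration > 0,
            pixel_size > 0, atrium_area > 0, ventricle_area > 0,
            contraction_atrium >= 0, contraction_atrium < 1,
            contraction_ventricle >= 0, contraction_ventricle < 1,
            avc_intensity_fraction > 0, avc_intensity_fraction < 1,
            noise_sd >= 0)
  as.list(environment())
}

# piecewise-linear beat phase through jittered beat-cycle boundaries
jittered_phase <- function(tt, freq, cv) {
  n_cycles <- ceiling(max(tt) * freq * 2) + 10
  sigma2 <- log(1 + cv^2)
  mu <- log(1 / freq) - sigma2 / 2
  intervals <- stats::rlnorm(n_cycles, mu, sqrt(sigma2))
  bounds <- c(0, cumsum(intervals))
  list(phase = stats::approx(bounds, 2 * pi * (seq_along(bounds) - 1),
                             xout = tt)$y,
       bounds = bounds)
}

resolve_rhythm <- function(p) {
  fa <- p$freq_atrium; fv <- p$freq_ventricle
  ma <- p$contraction_atrium; mv <- p$contraction_ventricle
  if (p$rhythm_mode == "block_2to1") fv <- fa / 2
  if (p$rhythm_mode == "flutter") {
    fa <- max(fa, 2 * fv)
    ma <- ma * 0.5
  }
  list(freq_atrium = fa, freq_ventricle = fv,
       m_atrium = ma, m_ventricle = mv)
}

#' Generate a synthetic fluorescence heartbeat video
#'
#' Renders two pulsing bright ellipses (atrium left, ventricle right) whose
#' areas follow `A(t) = A0 (1 - m (1 + sin(2 pi f t + phi)) / 2)`, joined
#' by a dimmer atrioventricular bridge, with additive seeded Gaussian pixel
#' noise. Both ellipse axes are scaled by the square root of the area
#' ratio so the analytic area follows the waveform exactly; ground truth is
#' read off the rendered binary masks. A beat frequency at or above the
#' Nyquist rate is rendered anyway (with a warning) so aliasing behavior
#' can be studied.
#'
#' @param params a [heart_sim_params()].
#' @return List with `stack` (a [frame_stack()]) and `truth`: per-frame
#'   chamber masks and areas (µm²), effective `freq_atrium` /
#'   `freq_ventricle` (1/s), atrial `beat_times` (s), `heart_size` (µm²,
#'   median of the first six frames), chamber `centers` and base `axes`
#'   (pixels), and the parameter list.
#' @export
generate_heart_video <- function(params = heart_sim_params()) {
  p <- params
  rhy <- resolve_rhythm(p)
  if (max(rhy$freq_atrium, rhy$freq_ventricle) >= p$frame_rate / 2)
    cb_warn("cb_nyquist_warning",
            "beat frequency at or above Nyquist (%.3g f/s); expect aliasing",
            p$frame_rate)
  n <- round(p$duration * p$frame_rate)
  tt <- (seq_len(n) - 1) / p$frame_rate
  W <- p$width; H <- p$height
  ps2 <- p$pixel_size^2
  aspect <- 1.3
  ax <- function(area_um2) {
    apx <- area_um2 / ps2
    a <- sqrt(apx * aspect / pi)
    c(a = a, b = a / aspect)
  }
  axA <- ax(p$atrium_area); axV <- ax(p$ventricle_area)
  cy <- H / 2
  cxa <- round(0.30 * W); cxv <- round(0.70 * W)
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  hh <- 4  # AVC half-height in pixels
  avc_band <- (Y >= cy - hh) & (Y <= cy + hh) & (X >= cxa) & (X <= cxv)

  with_seed(p$seed, {
    cycle_bounds <- NULL
    if (p$rhythm_mode == "irregular") {
      jp <- jittered_phase(tt, rhy$freq_atrium, p$irregular_jitter)
      phase_a <- jp$phase
      phase_v <- phase_a - p$phase_lag
      cycle_bounds <- jp$bounds
    } else {
      phase_a <- 2 * pi * rhy$freq_atrium * tt
      phase_v <- 2 * pi * rhy$freq_ventricle * tt - p$phase_lag
    }
    area_scale <- function(phase, m) 1 - m * (1 + sin(phase)) / 2
    sa <- area_scale(phase_a, rhy$m_atrium)
    sv <- area_scale(phase_v, rhy$m_ventricle)
    frames <- vector("list", n)
    masksA <- vector("list", n)
    masksV <- vector("list", n)
    for (i in seq_len(n)) {
      ka <- sqrt(sa[i]); kv <- sqrt(sv[i])
      mA <- ((X - cxa) / (axA["a"] * ka))^2 + ((Y - cy) / (axA["b"] * ka))^2 <= 1
      mV <- ((X - cxv) / (axV["a"] * kv))^2 + ((Y - cy) / (axV["b"] * kv))^2 <= 1
      f <- matrix(0, H, W)
      f[avc_band] <- p$avc_intensity_fraction * p$intensity
      f[mA | mV] <- p$intensity
      if (p$noise_sd > 0) f <- f + matrix(stats::rnorm(H * W, 0, p$noise_sd), H, W)
      frames[[i]] <- pmax(f, 0)
      masksA[[i]] <- mA
      masksV[[i]] <- mV
    }
  })

  areasA <- vapply(masksA, sum, numeric(1)) * ps2
  areasV <- vapply(masksV, sum, numeric(1)) * ps2
  # atrial beat times: peaks of the area waveform (phase = 3*pi/2 mod 2*pi),
  # i.e. three quarters through each beat cycle
  if (is.null(cycle_bounds)) {
    k <- 0:ceiling(p$duration * rhy$freq_atrium + 2)
    beat_times <- (3 * pi / 2 + 2 * pi * k) / (2 * pi * rhy$freq_atrium)
  } else {
    beat_times <- utils::head(cycle_bounds, -1) + 0.75 * diff(cycle_bounds)
  }
  beat_times <- beat_times[beat_times <= p$duration]
  stack <- frame_stack(frames, p$frame_rate, p$pixel_size,
                       source_id = sprintf("sim_seed%d", p$seed))
  truth <- list(
    masks = list(atrium = masksA, ventricle = masksV),
    areas = list(atrium = areasA, ventricle = areasV),
    freq_atrium = rhy$freq_atrium, freq_ventricle = rhy$freq_ventricle,
    beat_times = beat_times,
    heart_size = stats::median((areasA + areasV)[1:min(6, n)]),
    centers = list(atrium = c(x = cxa, y = cy), ventricle = c(x = cxv, y = cy)),
    axes = list(atrium = axA, ventricle = axV),
    contraction = c(atrium = rhy$m_atrium, ventricle = rhy$m_ventricle),
    params = p
  )
  list(stack = stack, truth = truth)
}

#' Generate a synthetic brightfield heartbeat video
#'
#' Brightfield contrast is motion, not fluorescence: a bright, statically
#' textured background with a small dark region whose area pulses at the
#' ventricular frequency. Used to exercise the automated brightfield
#' module.
#'
#' @inheritParams generate_heart_video
#' @return List with `stack` and `truth` (`freq`, per-frame dark-region
#'   masks, the parameter list).
#' @export
generate_bf_video <- function(params = heart_sim_params()) {
  p <- params
  rhy <- resolve_rhythm(p)
  if (rhy$freq_ventricle >= p$frame_rate / 2)
    cb_warn("cb_nyquist_warning", "beat frequency at or above Nyquist")
  n <- round(p$duration * p$frame_rate)
  tt <- (seq_len(n) - 1) / p$frame_rate
  W <- p$width; H <- p$height
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  cx <- W / 2; cy <- H / 2
  r0 <- sqrt((p$ventricle_area / p$pixel_size^2) / pi)
  with_seed(p$seed, {
    texture <- matrix(stats::runif(H * W, -0.05, 0.05) * p$intensity, H, W)
    base <- 0.9 * p$intensity + texture
    s <- 1 - rhy$m_ventricle * (1 + sin(2 * pi * rhy$freq_ventricle * tt)) / 2
    frames <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      m <- (X - cx)^2 + (Y - cy)^2 <= (r0 * sqrt(s[i]))^2
      f <- base
      f[m] <- f[m] - 0.5 * p$intensity
      if (p$noise_sd > 0) f <- f + matrix(stats::rnorm(H * W, 0, p$noise_sd), H, W)
      frames[[i]] <- pmax(f, 0)
      masks[[i]] <- m
    }
  })
  stack <- frame_stack(frames, p$frame_rate, p$pixel_size,
                       source_id = sprintf("bf_sim_seed%d", p$seed))
  list(stack = stack,
       truth = list(freq = rhy$freq_ventricle, masks = masks, params = p))
}

#' Generate a synthetic screen table with known hits
#'
#' Emulates the input of the screen statistics: per-embryo heart rates with
#' treatment labels, organized into experiments of at most 100 compounds
#' each with their own DMSO control group. A fraction of compounds is
#' spiked with an effect of `effect_z` fold-change standard deviations
#' (random sign).
#'
#' @param n_compounds number of compounds.
#' @param n_replicates embryos per compound.
#' @param hit_fraction fraction of compounds spiked, in `[0, 1]`.
#' @param effect_z spike size in units of the per-embryo fold-change SD.
#' @param seed RNG seed.
#' @param control_mean mean control heart rate, beats/min.
#' @param embryo_sd per-embryo heart-rate SD, beats/min.
#' @param controls_per_experiment DMSO embryos per experiment.
#' @return List: `table` (columns `embryo_id`, `compound`, `replicate`,
#'   `experiment_id`, `role`, `hr_bpm`) and `hits` (per-compound truth
#'   with spike sign).
#' @export
generate_screen_dataset <- function(n_compounds, n_replicates = 3,
                                    hit_fraction = 0.05, effect_z = 3,
                                    seed = 1L, control_mean = 160,
                                    embryo_sd = 8,
                                    controls_per_experiment = 8L) {
  stopifnot(hit_fraction >= 0, hit_fraction <= 1, n_compounds >= 1)
  n_exp <- max(1L, ceiling(n_compounds / 100))
  exp_of <- rep(seq_len(n_exp), length.out = n_compounds)
  with_seed(seed, {
    n_hits <- round(hit_fraction * n_compounds)
    hit_idx <- if (n_hits > 0) sample(n_compounds, n_hits) else integer(0)
    sign_of <- integer(n_compounds)
    sign_of[hit_idx] <- sample(c(-1L, 1L), n_hits, replace = TRUE)
    exp_shift <- stats::rnorm(n_exp, 0, 4)
    rows <- list()
    eid <- 0L
    for (ex in seq_len(n_exp)) {
      mu <- control_mean + exp_shift[ex]
      for (j in seq_len(controls_per_experiment)) {
        eid <- eid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          embryo_id = sprintf("e%05d", eid), compound = "DMSO",
          replicate = j, experiment_id = sprintf("exp%02d", ex),
          role = "control",
          hr_bpm = stats::rnorm(1, mu, embryo_sd))
      }
      for (ci in which(exp_of == ex)) {
        shift <- sign_of[ci] * effect_z * embryo_sd
        for (j in seq_len(n_replicates)) {
          eid <- eid + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            embryo_id = sprintf("e%05d", eid),
            compound = sprintf("cmpd%04d", ci),
            replicate = j, experiment_id = sprintf("exp%02d", ex),
            role = "compound",
            hr_bpm = stats::rnorm(1, mu + shift, embryo_sd))
        }
      }
    }
  })
  table <- do.call(rbind, rows)
  hits <- data.frame(compound = sprintf("cmpd%04d", seq_len(n_compounds)),
                     is_hit = seq_len(n_compounds) %in% hit_idx,
                     sign = sign_of)
  list(table = table, hits = hits)
}

#' Seed polygons from synthetic ground truth
#'
#' Builds rectangular chamber seeds centered on the true chamber centers
#' (sized to stay inside the chamber at maximal contraction), converted
#' into the coordinates of a detected ROI. A convenience for pipelines and
#' tests running on generated videos; real recordings take seeds from the
#' sidecar config.
#'
#' @param truth the `truth` element of [generate_heart_video()].
#' @param roi a [heart_roi()].
#' @return A [chamber_seeds()].
#' @export
seeds_from_truth <- function(truth, roi) {
  mk <- function(ch) {
    ctr <- truth$centers[[ch]]
    a <- truth$axes[[ch]]
    shrink <- sqrt(1 - truth$contraction[[ch]]) * 0.55
    dx <- a["a"] * shrink; dy <- a["b"] * shrink
    x <- ctr["x"] - roi$cols[1] + 1
    y <- ctr["y"] - roi$rows[1] + 1
    cbind(x = c(x - dx, x + dx, x + dx, x - dx),
          y = c(y - dy, y - dy, y + dy, y + dy))
  }
  chamber_seeds(atrium = mk("atrium"), ventricle = mk("ventricle"))
}
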