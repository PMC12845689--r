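# Forward simulation of complete synthetic PPG records and cohorts, with
# full ground truth retained for validation.

#' Generate baseline drift
#'
#' Baseline drift is the low-frequency (< 0.7 Hz) additive displacement of
#' the sensor relative to the artery.  It is synthesized as the sum of the
#' deterministic sinusoids in `sdof$drift_sins` plus (optionally) a
#' band-limited random walk: a cumulative Gaussian walk low-passed at
#' 0.35 Hz with a zero-phase Butterworth filter and rescaled to RMS
#' `sdof$drift_walk_amp`, which keeps essentially all drift power below
#' 0.7 Hz.
#'
#' @param sdof an [sdof_config()] carrying the drift specification.
#' @param fs sampling rate, Hz.
#' @param duration record length, s.
#' @param seed integer seed for the random-walk component.
#' @return `waveform` of the drift `x_b`.
#' @export
make_baseline_drift <- function(sdof, fs, duration, seed = NULL) {
  stopifnot(inherits(sdof, "sdof_config"), fs > 0, duration > 0)
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  xb <- numeric(n)
  ds <- sdof$drift_sins
  if (nrow(ds))
    for (j in seq_len(nrow(ds)))
      xb <- xb + ds$amp[j] * cos(2 * pi * ds$freq[j] * t + ds$phase[j])
  if (sdof$drift_walk_amp > 0) {
    walk <- with_seed(seed, cumsum(stats::rnorm(n)))
    walk <- lowpass_zp(walk, fs, 0.35, order = 4L)
    walk <- walk - mean(walk)
    rms <- sqrt(mean(walk^2))
    if (rms > 0) xb <- xb + walk * (sdof$drift_walk_amp / rms)
  }
  waveform(xb, fs)
}

#' Simulate a complete synthetic PPG record
#'
#' Composes the full forward model: true pulse `y` (see
#' [make_true_pulse()]) drives the contact stack under drift-coupled
#' time-varying parameters ([simulate_tcs()]); the sensor reads
#' `x_PPG = x_M + x_b + noise`.  The TVSP-generated distortion is isolated
#' by a second integration run with the coupling switched off:
#' `x_tvsp_true = x_M - x_M|gamma=0`.
#'
#' Sub-seeds `seed`, `seed + 1`, `seed + 2` drive the pulse PF process,
#' the drift walk and the sensor noise, so each component is individually
#' reproducible.
#'
#' @param spec a [pulse_spec()].
#' @param sdof an [sdof_config()].
#' @param fs sampling rate, Hz (default 125, the bedside-monitor
#'   convention).
#' @param duration record length, s.  The default 85 s leaves the 5 s
#'   integrator transient ahead of an 80 s analysis segment.
#' @param seed integer seed.
#' @param label ground-truth label, `"AF"` or `"non-AF"`.
#' @return object of class `ppg_record`: list with `ppg` (`waveform`) and
#'   `truth` (list of component waveforms `y`, `x_b`, `x_C`,
#'   `x_tvsp_true`, `x_noise_true`, the `pulse_truth` attribute of `y`,
#'   `spec`, `sdof`, `label`, `seed`).
#' @export
make_ppg <- function(spec, sdof, fs = 125, duration = 85, seed = 1,
                     label = c("non-AF", "AF")) {
  label <- match.arg(label)
  y <- make_true_pulse(spec, fs, duration, seed = seed)
  x_b <- make_baseline_drift(sdof, fs, duration, seed = seed + 1)
  x_M <- simulate_tcs(y, x_b, sdof)
  sdof0 <- sdof
  sdof0$gamma[] <- 0
  x_C <- simulate_tcs(y, x_b, sdof0)
  x_tvsp_true <- waveform(x_M$samples - x_C$samples, fs)
  noise <- with_seed(seed + 2,
                     stats::rnorm(length(y$samples), 0, sdof$noise_sd))
  ppg <- waveform(x_M$samples + x_b$samples + noise, fs)
  structure(list(
    ppg = ppg,
    truth = list(y = y, x_b = x_b, x_C = x_C, x_M = x_M,
                 x_tvsp_true = x_tvsp_true,
                 x_noise_true = waveform(noise, fs),
                 pulse_truth = attr(y, "pulse_truth"),
                 spec = spec, sdof = sdof, label = label, seed = seed)),
    class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %s, seed %d\n", x$truth$label, x$truth$seed))
  print(x$ppg)
  invisible(x)
}

# ---- cohort presets ---------------------------------------------------

# Draw one subject's generative parameters from the group preset.  These
# draws consume the current RNG stream; generate_cohort() seeds it per
# record.  Values are the package's standing study conditions: non-AF
# subjects have small coherent respiratory sinus arrhythmia, tiny
# non-harmonic HR variability, light drift and weak parameter coupling;
# AF subjects have large irregular beat-to-beat frequency variation
# (fast, strong PF process), harmonic-wise inconsistent respiratory
# modulation, drift of one-third to one-half of the pulse amplitude,
# stronger coupling and more sensor noise.
draw_preset <- function(group = c("non-AF", "AF"), overrides = list()) {
  group <- match.arg(group)
  p <- if (group == "non-AF") {
    list(f0 = stats::runif(1, 1.0, 1.5),
         A = c(1, 0.5, 0.25) * stats::runif(1, 0.8, 1.2),
         phi0 = c(0, 0.9, 0.4) + stats::rnorm(3, 0, 0.1),
         B = stats::runif(1, 0.02, 0.04),
         f_r = stats::runif(1, 0.2, 0.3),
         alpha0 = stats::runif(1, 0, 2 * pi),
         pf_sd = 0.005, pf_corr_time = 5, order_scaled = TRUE,
         gamma = c(m = 0.05, c = 0.10, k = 0.15),
         drift_sins = data.frame(freq = c(stats::runif(1, 0.05, 0.12),
                                          stats::runif(1, 0.20, 0.30)),
                                 amp = c(0.12, 0.04),
                                 phase = stats::runif(2, 0, 2 * pi)),
         drift_walk_amp = 0.03, noise_sd = 0.01)
  } else {
    list(f0 = stats::runif(1, 1.0, 1.8),
         A = c(1, 0.5, 0.25) * stats::runif(1, 0.8, 1.2),
         phi0 = c(0, stats::runif(1, 0.2, 1.2), stats::runif(1, 0.2, 1.2)),
         B = stats::runif(1, 0.05, 0.12) * stats::runif(3, 0.6, 1.4),
         f_r = stats::runif(1, 0.2, 0.3),
         alpha0 = stats::runif(3, 0, 2 * pi),
         pf_sd = stats::runif(1, 0.08, 0.15), pf_corr_time = 2,
         order_scaled = TRUE,
         gamma = c(m = 0.10, c = 0.25, k = 0.35),
         drift_sins = data.frame(freq = c(stats::runif(1, 0.04, 0.10),
                                          stats::runif(1, 0.20, 0.35)),
                                 amp = c(0.45, 0.16),
                                 phase = stats::runif(2, 0, 2 * pi)),
         drift_walk_amp = 0.10, noise_sd = 0.04)
  }
  p[names(overrides)] <- overrides
  p
}

preset_record <- function(group, overrides, fs, duration, seed, n_harmonics) {
  p <- with_seed(seed, draw_preset(group, overrides))
  spec <- pulse_spec(f0 = p$f0, A = p$A[seq_len(n_harmonics)],
                     phi0 = p$phi0, B = p$B, f_r = p$f_r,
                     alpha0 = p$alpha0, pf_sd = p$pf_sd,
                     pf_corr_time = p$pf_corr_time,
                     order_scaled = p$order_scaled)
  sdof <- sdof_config(gamma = p$gamma, drift_sins = p$drift_sins,
                      drift_walk_amp = p$drift_walk_amp,
                      noise_sd = p$noise_sd)
  make_ppg(spec, sdof, fs = fs, duration = duration, seed = seed,
           label = group)
}

#' Generate a synthetic AF / non-AF cohort
#'
#' Draws `n_af` atrial-fibrillation and `n_nonaf` non-AF records from the
#' group presets (see the preset description in the package vignette).
#' Every record is reproducible from `(seed, index)`: the cohort seed
#' deterministically assigns one sub-seed per record, and all of a
#' record's parameter draws and noise realizations derive from that
#' sub-seed.
#'
#' @param n_af,n_nonaf group sizes (non-negative integers).
#' @param preset_overrides optional list with elements `af` and/or
#'   `nonaf`, each a named list overriding preset fields (e.g.
#'   `list(nonaf = list(pf_sd = 0.05))`), and optionally `fs`,
#'   `duration`, `n_harmonics`.
#' @param seed cohort seed (integer).
#' @return list of [make_ppg()] records, AF first, with attribute
#'   `"record_seeds"`.
#' @export
generate_cohort <- function(n_af, n_nonaf, preset_overrides = list(),
                            seed = 1) {
  stopifnot(n_af >= 0, n_nonaf >= 0)
  n <- n_af + n_nonaf
  if (n == 0L) return(list())
  fs <- preset_overrides$fs %||% 125
  duration <- preset_overrides$duration %||% 85
  n_harmonics <- preset_overrides$n_harmonics %||% 3
  rec_seeds <- with_seed(seed, sample.int(2^30, n))
  groups <- c(rep("AF", n_af), rep("non-AF", n_nonaf))
  out <- vector("list", n)
  for (j in seq_len(n)) {
    ov <- if (groups[j] == "AF") preset_overrides$af else preset_overrides$nonaf
    out[[j]] <- preset_record(groups[j], ov %||% list(), fs, duration,
                              rec_seeds[j], n_harmonics)
  }
  attr(out, "record_seeds") <- rec_seeds
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
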