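# The end-to-end analysis: one call takes a raw PPG waveform through
# baseline removal, fundamental detection, harmonic isolation, Hilbert
# demodulation, reconstruction, cardiac and respiration metrics, and AF
# screening, returning a single classed object.

#' Full analysis configuration
#'
#' Bundles every stage's tunables.  See [preprocess_config()],
#' [decompose_config()] and [af_thresholds()] for the stage-level
#' parameters.
#'
#' @param n_harmonics number of heart-rate harmonics analyzed (default
#'   3; higher harmonics of arrhythmic records are too weak to track).
#' @param preprocess a [preprocess_config()].
#' @param decompose a [decompose_config()].
#' @param resp_band respiratory search band, Hz.
#' @param thresholds an [af_thresholds()].
#' @return object of class `sdof_tf_config`.
#' @export
sdof_tf_config <- function(n_harmonics = 3L,
                           preprocess = preprocess_config(),
                           decompose = decompose_config(),
                           resp_band = c(0.1, 0.6),
                           thresholds = af_thresholds()) {
  stopifnot(n_harmonics >= 1L)
  structure(list(n_harmonics = as.integer(n_harmonics),
                 preprocess = preprocess, decompose = decompose,
                 resp_band = resp_band, thresholds = thresholds),
            class = "sdof_tf_config")
}

#' Analyze an at-rest PPG record
#'
#' The main entry point: models and removes motion artifact (baseline
#' drift plus multiplicative distortion from drift-coupled contact-stack
#' parameters) and sensor noise, tracks each heart-rate harmonic's
#' instant amplitude/frequency/phase, reconstructs the arterial pulse
#' waveform, and extracts the heart-rate, heart-rate-variability and
#' respiration indices used for atrial-fibrillation screening.
#'
#' @param x a `waveform`, a [make_ppg()] record, or a numeric vector
#'   (then `fs` is required).
#' @param fs sampling rate in Hz when `x` is a plain vector.
#' @param segment optional `c(start_s, end_s)` analysis window on the
#'   record's time axis (inclusive start, exclusive end).  Pick a window
#'   free of abrupt signal changes; [flag_abrupt_changes()] can help.
#' @param config an [sdof_tf_config()].
#' @param label optional ground-truth label carried into the indices.
#' @return an object of class `sdof_tf` with components `f0_est`, `x0`,
#'   `x_b`, `decomposition`, `reconstruction`, `cardiac`, `resp`,
#'   `indices`, `verdict`, `votes`, `config`, `call`.  Methods:
#'   `print`, `summary`, `coef`, `plot`, `fitted` (the artifact-free
#'   reconstruction), `residuals` (the sensor-noise estimate) and
#'   `simulate` (synthetic records matched to the fitted indices).
#' @examples
#' rec <- make_ppg(pulse_spec(), sdof_config(noise_sd = 0.01), seed = 7)
#' fit <- sdof_tf(rec, segment = c(5, 85))
#' print(fit)
#' coef(fit)[c("HR", "SD_HR")]
#' @export
sdof_tf <- function(x, fs = NULL, segment = NULL,
                    config = sdof_tf_config(), label = NA_character_) {
  cl <- match.call()
  if (inherits(x, "ppg_record")) {
    if (is.na(label)) label <- x$truth$label
    x <- x$ppg
  }
  if (!is_waveform(x)) {
    if (is.null(fs)) stop("fs is required when x is not a waveform")
    x <- waveform(x, fs)
  }
  if (!is.null(segment)) x <- segment_waveform(x, segment[1], segment[2])

  pp <- config$preprocess
  bl <- remove_baseline(x, pp)
  f0 <- detect_fundamental(bl$x0, pp)
  tracks <- lapply(seq_len(config$n_harmonics), function(i) {
    hvd_track(isolate_harmonic(bl$x0, i, f0, pp), i, f0, config$decompose)
  })
  decomp <- assemble(bl$x0, tracks)
  recon <- reconstruct(decomp)
  cardiac <- cardiac_metrics(decomp, f0, config$resp_band)
  resp <- resp_metrics(decomp, config$resp_band)
  idx <- compute_indices(cardiac, resp, recon, label = label)
  cls <- classify_af(idx, config$thresholds)

  structure(list(f0_est = f0, x_ppg = x, x0 = bl$x0, x_b = bl$x_b,
                 decomposition = decomp, reconstruction = recon,
                 cardiac = cardiac, resp = resp, indices = idx,
                 verdict = cls$verdict, votes = cls$votes,
                 config = config, call = cl),
            class = "sdof_tf")
}

#' Flag windows containing abrupt amplitude changes
#'
#' A helper for segment selection: slides a window over the drift-free
#' signal and flags windows whose peak-to-peak amplitude jumps by more
#' than `jump_factor` between adjacent windows.  Windows not flagged are
#' candidates for analysis.
#'
#' @param w a `waveform` (raw or drift-free).
#' @param window_s window length, s.
#' @param jump_factor ratio of adjacent-window amplitudes counted as
#'   abrupt.
#' @return data frame with `start_s`, `end_s`, `amplitude`, `abrupt`.
#' @export
flag_abrupt_changes <- function(w, window_s = 5, jump_factor = 2) {
  stopifnot(is_waveform(w))
  n <- length(w$samples)
  step <- round(window_s * w$fs)
  starts <- seq(1L, n - step + 1L, by = step)
  amp <- vapply(starts, function(s) {
    seg <- w$samples[s:(s + step - 1L)]
    diff(range(seg))
  }, numeric(1))
  ratio <- c(1, amp[-1] / pmax(amp[-length(amp)], 1e-12))
  data.frame(start_s = (starts - 1) / w$fs + w$t0,
             end_s = (starts - 1 + step) / w$fs + w$t0,
             amplitude = amp,
             abrupt = ratio > jump_factor | ratio < 1 / jump_factor)
}

#' @export
print.sdof_tf <- function(x, ...) {
  cat("SDOF time-frequency PPG analysis\n")
  cat(sprintf("  segment: %.1f s @ %g Hz, f0 = %.3f Hz\n",
              wave_duration(x$x_ppg), x$x_ppg$fs, x$f0_est))
  cat(sprintf("  HR %.1f bpm  SD(HR) %.4f  HR_phi %.1f  SD(HR_phi) %.4f\n",
              x$cardiac$HR, x$cardiac$SD_HR,
              x$cardiac$HR_phi, x$cardiac$SD_HR_phi))
  cat(sprintf("  verdict: %s (votes: %s)\n", x$verdict,
              paste(names(x$votes)[which(x$votes)], collapse = ", ")))
  invisible(x)
}

#' @export
summary.sdof_tf <- function(object, ...) {
  structure(list(fit = object), class = "summary.sdof_tf")
}

#' @export
print.summary.sdof_tf <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-harmonic cardiac metrics (bpm):\n")
  print(f$cardiac$per_harmonic, row.names = FALSE, digits = 4)
  cat("\nRespiration (Hz):\n")
  print(f$resp$per_harmonic, row.names = FALSE, digits = 4)
  cat("\nPulse-waveform features:\n")
  cat("  amplitude ratios:", paste(signif(f$reconstruction$amp_ratio, 3),
                                   collapse = ", "), "\n")
  cat("  phase differences:", paste(signif(f$reconstruction$phase_diff, 3),
                                    collapse = ", "), "rad\n")
  cat(sprintf("  noise RMS / x0 RMS: %.3f\n", f$decomposition$noise_ratio))
  invisible(x)
}

#' @export
coef.sdof_tf <- function(object, ...) {
  idx <- object$indices
  c(HR = idx$HR, SD_HR = idx$SD_HR,
    HR_phi = idx$HR_phi, SD_HR_phi = idx$SD_HR_phi,
    stats::setNames(idx$rmse_hr, paste0("RMSE_HR_", names(idx$rmse_hr))),
    stats::setNames(idx$rmse_hr_phi,
                    paste0("RMSE_HR_phi_", names(idx$rmse_hr_phi))),
    stats::setNames(idx$mean_b_phi, paste0("B_phi_", names(idx$mean_b_phi))),
    RMSSD_x0 = idx$RMSSD_x0, RMSSD_x1 = idx$RMSSD_x1)
}

#' @export
fitted.sdof_tf <- function(object, ...) object$reconstruction$x_tf

#' @export
residuals.sdof_tf <- function(object, ...) object$decomposition$x_noise

#' Simulate records matched to a fitted analysis
#'
#' Generates synthetic PPG records whose pulse parameters follow the
#' fitted indices: fundamental at the measured HR, harmonic amplitudes
#' from the fitted amplitude ratios, initial phases from the mean instant
#' phases, respiration rate and modulation from the phase-track
#' estimates.  Useful as a parametric sanity check of the whole chain.
#'
#' @param object an [sdof_tf()] fit.
#' @param nsim number of records.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [make_ppg()] records.
#' @export
simulate.sdof_tf <- function(object, nsim = 1, seed = NULL, ...) {
  idx <- object$indices
  recon <- object$reconstruction
  A <- c(1, unname(recon$amp_ratio))
  spec <- pulse_spec(f0 = idx$HR / 60, A = A,
                     phi0 = c(recon$phi_bar[1],
                              recon$phi_bar[1] + unname(recon$phase_diff)),
                     B = unname(idx$mean_b_phi[1]),
                     f_r = unname(idx$rr_phi[1]),
                     pf_sd = max(0, unname(idx$rmse_hr[1]) / 60 / 2))
  sdof <- sdof_config(noise_sd = stats::sd(object$decomposition$x_noise$samples))
  seeds <- with_seed(seed, sample.int(2^30, nsim))
  lapply(seeds, function(s)
    make_ppg(spec, sdof, fs = object$x_ppg$fs, duration = 85, seed = s))
}

#' @export
plot.sdof_tf <- function(x, which = 1:4, ...) {
  op <- graphics::par(mfrow = c(min(length(which), 2),
                                ceiling(length(which) / 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t0 <- wave_time(x$x0)
  if (1 %in% which) {
    plot(wave_time(x$x_ppg), x$x_ppg$samples, type = "l", col = "grey40",
         xlab = "time (s)", ylab = "a.u.", main = "PPG and baseline drift")
    graphics::lines(wave_time(x$x_b), x$x_b$samples, col = "red")
  }
  if (2 %in% which) {
    tr <- x$decomposition$tracks[[1]]
    plot(tr$t, tr$A, type = "l", xlab = "time (s)", ylab = "A1(t) (a.u.)",
         main = "Instant amplitude, harmonic 1")
    graphics::lines(tr$t, x$reconstruction$A_tilde[[1]], col = "red")
  }
  if (3 %in% which) {
    tf <- x$reconstruction$x_tf
    cf <- x$reconstruction$x_cf
    plot(wave_time(tf), tf$samples, type = "l", xlab = "time (s)",
         ylab = "a.u.", main = "Reconstruction: x_tf vs x_cf")
    graphics::lines(wave_time(cf), cf$samples, col = "blue", lty = 2)
  }
  if (4 %in% which) {
    hs <- x$cardiac$hr_series
    tr <- x$decomposition$tracks
    plot(tr[[1]]$t, hs[[1]], type = "l", ylim = range(unlist(hs)),
         xlab = "time (s)", ylab = "HR (bpm)",
         main = "Per-harmonic instant HR")
    if (length(hs) > 1)
      for (j in 2:length(hs)) graphics::lines(tr[[j]]$t, hs[[j]], col = j)
  }
  invisible(x)
}

#' Analyze a synthetic cohort end to end
#'
#' Runs [sdof_tf()] on every record and assembles the [cohort_report()].
#'
#' @param records list of [make_ppg()] records (see [generate_cohort()]).
#' @param segment analysis window applied to each record (default
#'   `c(5, duration)`: skips the simulator's start-up transient).
#' @param config an [sdof_tf_config()].
#' @return list with `fits`, `indices` and `report`.
#' @export
analyze_cohort <- function(records, segment = NULL,
                           config = sdof_tf_config()) {
  fits <- lapply(records, function(r) {
    seg <- segment %||% c(5, wave_duration(r$ppg))
    sdof_tf(r, segment = seg, config = config)
  })
  indices <- lapply(fits, `[[`, "indices")
  list(fits = fits, indices = indices,
       report = cohort_report(indices, config$thresholds))
}
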