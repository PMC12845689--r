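# Heart rate and heart-rate variability, read two ways: from the instant
# frequency of each harmonic (total HRV: respiration + other physiological
# factors + residual artifact) and from the instant initial phase
# (respiration-only HRV, nearly immune to artifact).  A classical
# time-domain per-cycle analysis is kept as a baseline.

#' Heart rate and HRV from a harmonic's instant frequency
#'
#' `HR_i(t) = 60 f_i(t) / i` (dividing by the order makes every harmonic
#' estimate the same physiological heart rate); the associated HRV is the
#' root-mean-square deviation of `HR_i(t)` about its own temporal mean.
#'
#' @param track a [hvd_track()] result.
#' @return list with `hr` (bpm series), `mean_hr` (bpm) and `rmse_hr`
#'   (bpm).
#' @export
hr_from_frequency <- function(track) {
  stopifnot(inherits(track, "harmonic_track"))
  hr <- 60 * track$f / track$order
  m <- mean(hr)
  list(hr = hr, mean_hr = m, rmse_hr = sqrt(mean((hr - m)^2)))
}

#' Subject-level heart rate across harmonics
#'
#' The subject's HR is the mean over harmonics of each harmonic's mean
#' HR; the across-harmonic spread is their sample standard deviation
#' (n-1 denominator).  Harmonics of one fundamental must agree, so this
#' spread is a sensitive indicator of artifact- or arrhythmia-induced
#' inconsistency between harmonics.
#'
#' @param tracks list of at least two [hvd_track()] results.
#' @return list with `HR` (bpm) and `SD_HR` (bpm).
#' @export
hr_summary <- function(tracks) {
  stopifnot(length(tracks) >= 2L)
  means <- vapply(tracks, function(tr) hr_from_frequency(tr)$mean_hr,
                  numeric(1))
  list(HR = mean(means), SD_HR = stats::sd(means))
}

#' Respiration-only heart rate from a harmonic's instant initial phase
#'
#' The respiratory frequency deviation is recovered from the phase
#' residual: `delta_f(t) = d/dt BP[phi0](t) / 2pi`, where `BP` is an
#' exactly zero-phase respiratory-band filter.  The series
#' `HR_phi_i(t) = 60 (f_mean + delta_f(t)) / i` then carries only the
#' breathing-synchronous part of heart-rate variability, and its RMS
#' deviation about its mean is the respiration-only HRV.
#'
#' @param track a [hvd_track()] result.
#' @param resp_band respiratory search band, Hz.
#' @return list with `hr` (bpm series), `mean_hr`, `rmse_hr` (bpm) and
#'   `reliable` (FALSE when the band is empty, in which case the series
#'   is the constant `60 f_mean / i`).
#' @export
hr_from_phase <- function(track, resp_band = c(0.1, 0.6)) {
  stopifnot(inherits(track, "harmonic_track"))
  p <- bandpass_fft(track$phi0, track$fs, resp_band[1], resp_band[2])
  reliable <- sqrt(mean(p^2)) > 1e-4
  if (!reliable) {
    hr <- rep(60 * track$f_mean / track$order, length(track$phi0))
    return(list(hr = hr, mean_hr = hr[1], rmse_hr = 0, reliable = FALSE))
  }
  df <- gradient4(p, 1 / track$fs) / (2 * pi)
  hr <- 60 * (track$f_mean + df) / track$order
  m <- mean(hr)
  list(hr = hr, mean_hr = m, rmse_hr = sqrt(mean((hr - m)^2)),
       reliable = TRUE)
}

#' Subject-level respiration-only heart rate across harmonics
#' @inheritParams hr_summary
#' @param resp_band respiratory search band, Hz.
#' @return list with `HR_phi` (bpm) and `SD_HR_phi` (bpm).
#' @export
hr_phase_summary <- function(tracks, resp_band = c(0.1, 0.6)) {
  stopifnot(length(tracks) >= 2L)
  means <- vapply(tracks,
                  function(tr) hr_from_phase(tr, resp_band)$mean_hr,
                  numeric(1))
  list(HR_phi = mean(means), SD_HR_phi = stats::sd(means))
}

#' Segment pulse cycles in the time domain
#'
#' Cycle onsets are the local minima preceding each steepest upstroke.
#' Upstrokes are detected as prominent peaks of the (lightly smoothed)
#' derivative with a refractory period of `0.4 / f0_est` seconds; each
#' onset is the signal minimum in the window before its upstroke.  The
#' piecewise-linear baseline through the onsets is returned for plotting.
#'
#' @param x pulse-like `waveform` (the drift-free signal or a single
#'   harmonic).
#' @param f0_est fundamental frequency, Hz.
#' @return list with `onsets` (sample indices into `x`), `times`
#'   (seconds), `baseline` (piecewise-linear baseline samples) and
#'   `hr` (per-cycle heart rate, bpm).
#' @export
segment_cycles <- function(x, f0_est) {
  stopifnot(is_waveform(x), f0_est > 0)
  fs <- x$fs
  s <- x$samples
  ds <- lowpass_zp(gradient4(s, 1 / fs), fs, 10, 2L)
  refr <- as.integer(max(3, round(0.4 / f0_est * fs)))
  thr <- 0.5 * stats::quantile(ds, 0.98)
  if (!is.finite(thr) || thr <= 0 || max(ds) <= 0)
    stop("no upstrokes found: signal appears flat")
  n <- length(ds)
  cand <- which(ds > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[ds[cand] >= ds[cand - 1] & ds[cand] >= ds[cand + 1]]
  # enforce refractory period, keeping the larger peak
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) && i - peaks[length(peaks)] < refr) {
      if (ds[i] > ds[peaks[length(peaks)]]) peaks[length(peaks)] <- i
    } else peaks <- c(peaks, i)
  }
  if (length(peaks) < 5L)
    stop("fewer than 5 pulse cycles detected")
  onsets <- vapply(peaks, function(p) {
    a <- max(1L, p - refr)
    a - 1L + which.min(s[a:p])
  }, integer(1))
  onsets <- unique(onsets)
  if (length(onsets) < 5L) stop("fewer than 5 pulse cycles detected")
  times <- wave_time(x)[onsets]
  baseline <- stats::approx(onsets, s[onsets], xout = seq_along(s),
                            rule = 2)$y
  list(onsets = onsets, times = times, baseline = baseline,
       hr = 60 / diff(times))
}

#' Root mean square of successive differences
#'
#' The classical time-domain HRV index, applied to a per-cycle heart-rate
#' series (bpm).
#'
#' @param hr_series per-cycle heart rates, bpm (at least 3 cycles).
#' @return RMSSD in bpm.
#' @export
rmssd <- function(hr_series) {
  hr_series <- as.numeric(hr_series)
  if (length(hr_series) < 3L) stop("need at least 3 cycles for RMSSD")
  sqrt(mean(diff(hr_series)^2))
}

#' All cardiac metrics for one decomposition
#'
#' Bundles the frequency-track and phase-track HR/HRV indices with the
#' time-domain baseline computed on the drift-free signal `x0` and on the
#' first harmonics.
#'
#' @param decomp a [assemble()] result.
#' @param f0_est fundamental frequency, Hz.
#' @param resp_band respiratory band, Hz.
#' @return object of class `cardiac_metrics`.
#' @export
cardiac_metrics <- function(decomp, f0_est, resp_band = c(0.1, 0.6)) {
  stopifnot(inherits(decomp, "ppg_decomposition"))
  tracks <- decomp$tracks
  byf <- lapply(tracks, hr_from_frequency)
  byp <- lapply(tracks, hr_from_phase, resp_band = resp_band)
  s1 <- hr_summary(tracks)
  s2 <- hr_phase_summary(tracks, resp_band)
  td <- list()
  rms_sd <- c()
  signals <- c(list(x0 = decomp$x0),
               stats::setNames(
                 lapply(tracks, function(tr) waveform(tr$x, tr$fs, tr$t[1])),
                 paste0("x", vapply(tracks, function(tr) tr$order, numeric(1)))))
  for (nm in names(signals)) {
    seg <- try(segment_cycles(signals[[nm]], f0_est), silent = TRUE)
    if (!inherits(seg, "try-error")) {
      td[[nm]] <- seg
      rms_sd[nm] <- rmssd(seg$hr)
    } else rms_sd[nm] <- NA_real_
  }
  structure(list(
    per_harmonic = data.frame(
      order = vapply(tracks, function(tr) tr$order, numeric(1)),
      mean_hr = vapply(byf, `[[`, numeric(1), "mean_hr"),
      rmse_hr = vapply(byf, `[[`, numeric(1), "rmse_hr"),
      mean_hr_phi = vapply(byp, `[[`, numeric(1), "mean_hr"),
      rmse_hr_phi = vapply(byp, `[[`, numeric(1), "rmse_hr")),
    hr_series = lapply(byf, `[[`, "hr"),
    hr_phi_series = lapply(byp, `[[`, "hr"),
    HR = s1$HR, SD_HR = s1$SD_HR,
    HR_phi = s2$HR_phi, SD_HR_phi = s2$SD_HR_phi,
    td = td, RMSSD = rms_sd),
    class = "cardiac_metrics")
}

#' @export
print.cardiac_metrics <- function(x, ...) {
  cat(sprintf("<cardiac_metrics> HR = %.1f bpm (SD across harmonics %.4f)\n",
              x$HR, x$SD_HR))
  cat(sprintf("  HR_phi = %.1f bpm (SD %.4f)\n", x$HR_phi, x$SD_HR_phi))
  print(x$per_harmonic, row.names = FALSE)
  cat("  RMSSD (bpm):",
      paste(sprintf("%s=%.2f", names(x$RMSSD), x$RMSSD), collapse = ", "),
      "\n")
  invisible(x)
}
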