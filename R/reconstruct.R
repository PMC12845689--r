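# Motion-artifact removal and arterial-pulse-waveform reconstruction.
# The multiplicative TVSP distortion lives almost entirely in the instant
# amplitude, so replacing each harmonic's envelope by its regression line
# (and its wandering initial phase by its mean) strips the artifact while
# keeping the physiological frequency modulation.

#' Straight-line amplitude trend of a harmonic
#'
#' Ordinary least-squares line fit of the instant amplitude against time,
#' evaluated on the track's own time base.
#'
#' @param track a [hvd_track()] result.
#' @return numeric vector, the fitted line \eqn{\tilde A_i(t)}.
#' @export
amplitude_trend <- function(track) {
  stopifnot(inherits(track, "harmonic_track"))
  tau <- track$t - track$t[1]
  fit <- stats::lm.fit(cbind(1, tau), track$A)
  as.numeric(cbind(1, tau) %*% fit$coefficients)
}

#' Mean instant initial phase of a harmonic
#'
#' Mean of the unwrapped instant initial phase, reported wrapped into
#' \eqn{(-\pi, \pi]}.  Unwrapping first makes the mean circular-safe for
#' sequences that straddle the branch cut.
#'
#' @param track a [hvd_track()] result, or a numeric phase vector (rad).
#' @return scalar phase in \eqn{(-\pi, \pi]}.
#' @export
phase_mean <- function(track) {
  ph <- if (inherits(track, "harmonic_track")) track$phi0 else as.numeric(track)
  wrap_pi(mean(as.numeric(signal::unwrap(ph))))
}

# Common anchored phase base for the reconstructions.  Each harmonic's
# accumulated phase is 2*pi*cumint(f_i) + c_i + phi_bar with the
# integration constant c_i chosen so that the *total* argument at the
# segment midpoint equals the track's unwrapped analytic phase there;
# this pins x_tf to x_HVD so their residual is pure artifact + noise
# rather than a constant phase offset.
anchored_phase <- function(track, phi_bar) {
  mid <- ceiling(length(track$t) / 2)
  ci <- cumtrapz1(track$f, 1 / track$fs)
  c_i <- track$Phi[mid] - 2 * pi * ci[mid] - phi_bar
  2 * pi * ci + c_i + phi_bar
}

#' Reconstruct the artifact- and noise-free pulse (time-varying frequency)
#'
#' \deqn{x_{tf}(t) = \sum_i \tilde A_i(t)\cos\big(2\pi{\textstyle\int}f_i\,dt + \bar\phi_{0i}\big)}
#' keeps each harmonic's measured frequency modulation (heart-rate
#' variability) but replaces the artifact-swung envelope by its regression
#' line and the initial phase by its mean.
#'
#' @param tracks list of [hvd_track()] results on a common time base.
#' @param A_tilde list of regression-line amplitudes (defaults to
#'   [amplitude_trend()] of each track).
#' @param phi_bar numeric vector of mean initial phases (defaults to
#'   [phase_mean()] of each track).
#' @return `waveform` of `x_tf`.
#' @export
reconstruct_tf <- function(tracks,
                           A_tilde = lapply(tracks, amplitude_trend),
                           phi_bar = vapply(tracks, phase_mean, numeric(1))) {
  x <- 0
  for (j in seq_along(tracks)) {
    ph <- anchored_phase(tracks[[j]], phi_bar[j])
    x <- x + A_tilde[[j]] * cos(ph)
  }
  waveform(x, tracks[[1]]$fs, tracks[[1]]$t[1])
}

#' Reconstruct the constant-frequency pulse
#'
#' Same amplitude lines and mean phases as [reconstruct_tf()], but each
#' harmonic runs at a constant frequency: by default the harmonic's own
#' segment-mean instant frequency (the measured constant heart rate), or
#' `i * f0_est` when `f0_est` is supplied.  Comparing `x_cf` with `x_tf`
#' shows what heart-rate variability does to the pulse shape.
#'
#' @inheritParams reconstruct_tf
#' @param f0_est optional fundamental frequency (Hz) forcing harmonic *i*
#'   to `i * f0_est`.
#' @return `waveform` of `x_cf`.
#' @export
reconstruct_cf <- function(tracks,
                           A_tilde = lapply(tracks, amplitude_trend),
                           phi_bar = vapply(tracks, phase_mean, numeric(1)),
                           f0_est = NULL) {
  x <- 0
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    tau <- tr$t - tr$t[1]
    mid <- ceiling(length(tau) / 2)
    fc <- if (is.null(f0_est)) tr$f_mean else tr$order * f0_est
    # anchored at the midpoint exactly like the time-varying reconstruction
    ph <- 2 * pi * fc * (tau - tau[mid]) + tr$Phi[mid]
    x <- x + A_tilde[[j]] * cos(ph)
  }
  waveform(x, tracks[[1]]$fs, tracks[[1]]$t[1])
}

#' Full reconstruction of a decomposition
#'
#' Computes the per-harmonic amplitude regression lines and mean initial
#' phases, the two reconstructed pulses, the TVSP distortion estimate
#' `x_tvsp = x_HVD - x_tf`, and the arterial-pulse-waveform features.
#'
#' @param decomp a [assemble()] result.
#' @param f0_est optional fundamental for the constant-frequency
#'   reconstruction (default: per-harmonic mean frequency).
#' @return object of class `ppg_reconstruction` with fields `A_tilde`,
#'   `phi_bar`, `x_tf`, `x_cf`, `x_tvsp`, `amp_ratio`, `phase_diff`,
#'   `phase_flag` (is \eqn{\bar\phi_{03} > \bar\phi_{02}}).
#' @export
reconstruct <- function(decomp, f0_est = NULL) {
  stopifnot(inherits(decomp, "ppg_decomposition"))
  tracks <- decomp$tracks
  A_tilde <- lapply(tracks, amplitude_trend)
  phi_bar <- vapply(tracks, phase_mean, numeric(1))
  x_tf <- reconstruct_tf(tracks, A_tilde, phi_bar)
  x_cf <- reconstruct_cf(tracks, A_tilde, phi_bar, f0_est = f0_est)
  x_tvsp <- waveform(decomp$x_HVD$samples - x_tf$samples,
                     x_tf$fs, x_tf$t0)
  orders <- vapply(tracks, function(tr) as.numeric(tr$order), numeric(1))
  feats <- apw_features_internal(A_tilde, phi_bar, orders)
  structure(c(list(A_tilde = A_tilde, phi_bar = phi_bar,
                   x_tf = x_tf, x_cf = x_cf, x_tvsp = x_tvsp,
                   tracks = tracks), feats),
            class = "ppg_reconstruction")
}

apw_features_internal <- function(A_tilde, phi_bar, orders) {
  if (length(A_tilde) < 2L)
    return(list(amp_ratio = numeric(0), phase_diff = numeric(0),
                phase_flag = NA))
  mA <- vapply(A_tilde, mean, numeric(1))
  amp_ratio <- mA[-1] / mA[1]
  names(amp_ratio) <- paste0("h", orders[-1])
  phase_diff <- wrap_pi(phi_bar[-1] - phi_bar[1])
  names(phase_diff) <- paste0("h", orders[-1])
  flag <- if (length(phi_bar) >= 3L) phi_bar[3] > phi_bar[2] else NA
  list(amp_ratio = amp_ratio, phase_diff = phase_diff, phase_flag = flag)
}

#' Arterial-pulse-waveform harmonic features
#'
#' Harmonic amplitudes normalized to the first harmonic and initial-phase
#' differences relative to the first harmonic, plus the flag
#' \eqn{\bar\phi_{03} > \bar\phi_{02}} (in some AF subjects the third
#' harmonic's initial phase overtakes the second's, which interacts with
#' dicrotic-notch preservation).
#'
#' @param recon a [reconstruct()] result.
#' @return list with `amp_ratio`, `phase_diff` (both for harmonics
#'   `2..N`) and `phase_flag`.
#' @export
apw_features <- function(recon) {
  stopifnot(inherits(recon, "ppg_reconstruction"))
  recon[c("amp_ratio", "phase_diff", "phase_flag")]
}

#' @export
print.ppg_reconstruction <- function(x, ...) {
  cat(sprintf("<ppg_reconstruction> %d harmonics\n", length(x$A_tilde)))
  cat(sprintf("  amp ratios: %s\n",
              paste(signif(x$amp_ratio, 3), collapse = ", ")))
  cat(sprintf("  phase diffs: %s rad (phi03 > phi02: %s)\n",
              paste(signif(x$phase_diff, 3), collapse = ", "),
              x$phase_flag))
  cat(sprintf("  RMS x_tvsp / RMS x_tf = %.3g\n",
              sqrt(mean(x$x_tvsp$samples^2)) / sqrt(mean(x$x_tf$samples^2))))
  invisible(x)
}

#' Export a reconstruction as a multi-column data frame
#' @param recon a [reconstruct()] result.
#' @param decomp the matching [assemble()] result.
#' @export
reconstruction_as_data_frame <- function(recon, decomp) {
  data.frame(t = wave_time(recon$x_tf),
             x0 = decomp$x0$samples,
             x_HVD = decomp$x_HVD$samples,
             x_tf = recon$x_tf$samples,
             x_cf = recon$x_cf$samples,
             x_tvsp = recon$x_tvsp$samples,
             x_noise = decomp$x_noise$samples)
}
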