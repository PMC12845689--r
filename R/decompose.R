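# Hilbert demodulation of each isolated harmonic into instant amplitude,
# instant frequency and instant initial phase, and the sensor-noise
# estimate that falls out of the decomposition.

#' Decomposition configuration
#'
#' @param freq_smooth_cutoff zero-phase low-pass cutoff (Hz) applied to
#'   the raw phase-derivative when forming the instant frequency.  The
#'   default 0.5 Hz suppresses derivative noise while retaining
#'   respiratory-band frequency modulation.
#' @param track_smooth_cutoff zero-phase low-pass cutoff (Hz) applied to
#'   the instant amplitude and instant initial phase.  Physiological and
#'   artifact-driven modulation of a harmonic lives below the pulse
#'   fundamental; ripple faster than this (residual neighbour-harmonic
#'   leakage, sensor noise beating) is excluded from the harmonic signal
#'   and therefore ends up in the sensor-noise estimate.
#' @param edge_trim seconds trimmed from each end of every track: covers
#'   the end effects of the Hilbert transform and the settle regions of
#'   the track smoothers.
#' @param weak_eps envelope floor, as a fraction of the peak envelope,
#'   below which samples count toward the weak-harmonic flag (raised when
#'   more than 10% of the track sits under the floor).
#' @return object of class `decompose_config`.
#' @export
decompose_config <- function(freq_smooth_cutoff = 0.5,
                             track_smooth_cutoff = 0.9, edge_trim = 4,
                             weak_eps = 0.05) {
  stopifnot(freq_smooth_cutoff > 0, track_smooth_cutoff > 0,
            edge_trim >= 0, weak_eps > 0)
  structure(list(freq_smooth_cutoff = freq_smooth_cutoff,
                 track_smooth_cutoff = track_smooth_cutoff,
                 edge_trim = edge_trim, weak_eps = weak_eps),
            class = "decompose_config")
}

#' Track one harmonic's instant amplitude, frequency and initial phase
#'
#' The analytic signal of the band-isolated harmonic gives the raw
#' envelope and unwrapped phase `Phi(t)`.  The instant frequency is the
#' smoothed phase derivative, `f(t) = LP[dPhi/dt] / 2pi`; the instant
#' initial phase is the detrended phase residual about the segment-mean
#' frequency, `phi0(t) = Phi(t) - 2 pi f_mean (t - t_start)`, which
#' isolates the slowly varying (integrated-respiration) part of the
#' phase.  Amplitude and initial phase are then low-passed below the
#' pulse fundamental (see [decompose_config()]), and the harmonic signal
#' is rebuilt from the smoothed tracks,
#' `x_i(t) = A(t) cos(2 pi f_mean (t - t_start) + phi0(t))`, so that
#' fast ripple is left to the noise estimate.  All tracks are
#' edge-trimmed.
#'
#' @param x_sd_i isolated harmonic `waveform` (see [isolate_harmonic()]).
#' @param i harmonic order.
#' @param f0_est fundamental frequency estimate, Hz (carried as
#'   provenance).
#' @param cfg a [decompose_config()].
#' @return object of class `harmonic_track`: list with `order`, `t`, `A`,
#'   `f`, `phi0`, `Phi` (unwrapped analytic phase), `x` (the harmonic
#'   signal on the trimmed base), `fs`, `f_mean`, `flagged` (weak
#'   harmonic), and `smooth` (the frequency-smoothing parameters, used
#'   for attenuation book-keeping).
#' @export
hvd_track <- function(x_sd_i, i, f0_est = NULL, cfg = decompose_config()) {
  stopifnot(is_waveform(x_sd_i), inherits(cfg, "decompose_config"))
  fs <- x_sd_i$fs
  x <- x_sd_i$samples
  n <- length(x)
  t <- wave_time(x_sd_i)
  # the FFT Hilbert transform assumes circular continuation; computing it
  # on an AR-extended copy keeps that discontinuity out of the record
  npad <- min(n - 1L, round(3 * fs))
  z <- analytic_signal(extend_ar(x, npad))[(npad + 1):(npad + n)]
  A_raw <- Mod(z)
  Phi <- as.numeric(signal::unwrap(Arg(z)))
  f_raw <- gradient4(Phi, 1 / fs) / (2 * pi)
  f_sm <- lowpass_zp(f_raw, fs, cfg$freq_smooth_cutoff, 4L)

  ntrim <- round(cfg$edge_trim * fs)
  keep <- if (ntrim > 0 && n > 2 * ntrim + 10) (ntrim + 1):(n - ntrim)
          else seq_len(n)
  tau <- t - t[1]            # phase reference: segment start (t_ref)
  # mean frequency from the smoother-settled core: an O(5e-5 Hz) edge
  # bias would tilt the detrended phase visibly over an 80 s segment
  ncore <- max(round(3 / cfg$freq_smooth_cutoff * fs), ntrim)
  core <- if (n > 2 * ncore + 10) (ncore + 1):(n - ncore) else keep
  f_mean <- mean(f_sm[core])
  phi0 <- Phi - 2 * pi * f_mean * tau
  A_sm <- lowpass_zp(A_raw, fs, cfg$track_smooth_cutoff, 4L)
  phi0_sm <- lowpass_zp(phi0, fs, cfg$track_smooth_cutoff, 4L)
  Phi_sm <- 2 * pi * f_mean * tau + phi0_sm
  x_i <- A_sm * cos(Phi_sm)

  A <- A_sm[keep]
  flagged <- mean(A < cfg$weak_eps * max(A)) > 0.10
  if (flagged)
    warning(sprintf("harmonic %d: envelope collapses over >10%% of the segment",
                    i), call. = FALSE)
  structure(list(order = i, t = t[keep], t_ref = t[1], A = A,
                 f = f_sm[keep],
                 phi0 = phi0_sm[keep], Phi = Phi_sm[keep], x = x_i[keep],
                 fs = fs, f_mean = f_mean, f0_est = f0_est,
                 flagged = flagged,
                 smooth = list(cutoff = cfg$freq_smooth_cutoff, order = 4L)),
            class = "harmonic_track")
}

#' @export
print.harmonic_track <- function(x, ...) {
  cat(sprintf("<harmonic_track> order %d, %d samples @ %g Hz\n",
              x$order, length(x$A), x$fs))
  cat(sprintf("  f_mean = %.4f Hz (%.1f bpm/order), mean A = %.4g%s\n",
              x$f_mean, 60 * x$f_mean / x$order, mean(x$A),
              if (isTRUE(x$flagged)) " [weak]" else ""))
  invisible(x)
}

#' Amplitude attenuation of the frequency smoother at a given frequency
#'
#' The instant frequency is smoothed with a zero-phase Butterworth
#' low-pass; modulation at frequency `f` (e.g. respiratory FM at the
#' respiration rate) survives with this gain.  Useful for bias-correcting
#' respiration modulation read off the frequency track.
#'
#' @param track a [hvd_track()] result.
#' @param f frequency (Hz) at which to evaluate the gain.
#' @return amplitude gain in (0, 1].
#' @export
freq_smoothing_gain <- function(track, f) {
  stopifnot(inherits(track, "harmonic_track"))
  # |H|^2 of an order-n Butterworth applied forward and backward
  1 / (1 + (f / track$smooth$cutoff)^(2 * track$smooth$order))
}

#' Assemble harmonic tracks into a decomposition
#'
#' `x_HVD` is the sample-wise sum of the harmonic signals and `x_noise`
#' is the residual `x0 - x_HVD` on the common trimmed time base; both
#' identities hold exactly by construction.
#'
#' @param x0 the baseline-free `waveform` the harmonics were isolated
#'   from.
#' @param tracks list of [hvd_track()] results covering orders
#'   `1..N` on a common trimmed time base.
#' @return object of class `ppg_decomposition` with `x0` (trimmed),
#'   `tracks`, `x_HVD`, `x_noise` and `noise_ratio`
#'   (RMS(x_noise)/RMS(x0)).
#' @export
assemble <- function(x0, tracks) {
  stopifnot(is_waveform(x0), length(tracks) >= 1L)
  lens <- vapply(tracks, function(tr) length(tr$x), integer(1))
  if (length(unique(lens)) != 1L)
    stop("harmonic tracks differ in length; decompose on a common segment")
  t_track <- tracks[[1]]$t
  t0_all <- wave_time(x0)
  idx <- match(round(t_track * x0$fs), round(t0_all * x0$fs))
  if (anyNA(idx))
    stop("track time base is not aligned with x0's sampling grid")
  x0_trim <- x0$samples[idx]
  x_hvd <- Reduce(`+`, lapply(tracks, `[[`, "x"))
  x_noise <- x0_trim - x_hvd
  structure(list(
    x0 = waveform(x0_trim, x0$fs, t_track[1]),
    tracks = tracks,
    x_HVD = waveform(x_hvd, x0$fs, t_track[1]),
    x_noise = waveform(x_noise, x0$fs, t_track[1]),
    noise_ratio = sqrt(mean(x_noise^2)) / sqrt(mean(x0_trim^2))),
    class = "ppg_decomposition")
}

#' @export
print.ppg_decomposition <- function(x, ...) {
  cat(sprintf("<ppg_decomposition> %d harmonics, noise RMS = %.1f%% of x0\n",
              length(x$tracks), 100 * x$noise_ratio))
  for (tr in x$tracks) print(tr)
  invisible(x)
}

#' Export harmonic tracks as a data frame
#'
#' One row per sample per harmonic, columns `t`, `order`, `A`, `f`,
#' `phi0` -- convenient for CSV export and plotting.
#' @param decomp a [assemble()] result.
#' @export
tracks_as_data_frame <- function(decomp) {
  stopifnot(inherits(decomp, "ppg_decomposition"))
  do.call(rbind, lapply(decomp$tracks, function(tr)
    data.frame(t = tr$t, order = tr$order, A = tr$A, f = tr$f,
               phi0 = tr$phi0)))
}
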