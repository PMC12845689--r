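# Respiration rate and respiration modulation from the harmonic tracks.
# Both the instant frequency and the instant initial phase carry the
# breathing rhythm, but the phase residual is far more robust to motion
# artifact, so respiration modulation is read from the phase only.

resp_if_series <- function(r, fs, smooth_cutoff = 0.1) {
  z <- analytic_signal(r)
  phi <- as.numeric(signal::unwrap(Arg(z)))
  f <- gradient4(phi, 1 / fs) / (2 * pi)
  list(freq = lowpass_zp(f, fs, smooth_cutoff, 2L), env = Mod(z))
}

# central window over which scalar means are taken (instantaneous rate and
# envelope estimates are least reliable near the segment ends)
central_idx <- function(n, frac = 0.6) {
  k <- floor(n * (1 - frac) / 2)
  (k + 1):(n - k)
}

#' Respiration rate from a harmonic's instant frequency
#'
#' Bandpasses the instant-frequency fluctuation to the respiratory band
#' and reads the instantaneous rate of the resulting narrow-band signal
#' from its analytic phase.  When respiratory power in the band is below
#' the floor the series is flagged unreliable.
#'
#' @param track a [hvd_track()] result.
#' @param resp_band respiratory band, Hz.
#' @param power_floor minimum in-band RMS frequency deviation (Hz).
#' @return list with `rr` (instant respiration-rate series, Hz),
#'   `mean_rr` (Hz, over the central 60% of the segment) and `reliable`.
#' @export
respiration_from_frequency <- function(track, resp_band = c(0.1, 0.6),
                                       power_floor = 2e-3) {
  stopifnot(inherits(track, "harmonic_track"))
  r <- bandpass_fft(track$f - track$f_mean, track$fs,
                    resp_band[1], resp_band[2])
  if (sqrt(mean(r^2)) < power_floor)
    return(list(rr = rep(NA_real_, length(r)), mean_rr = NA_real_,
                reliable = FALSE))
  s <- resp_if_series(r, track$fs)
  idx <- central_idx(length(r))
  list(rr = s$freq, mean_rr = mean(s$freq[idx]), reliable = TRUE)
}

#' Respiration rate and modulation from a harmonic's instant initial phase
#'
#' The respiratory component of the phase residual is
#' \eqn{p(t) \approx (s_i B/f_r)\sin(2\pi f_r t + \alpha)}: integrating a
#' frequency modulation of amplitude B at rate f_r yields a phase
#' oscillation of amplitude B/f_r.  The instantaneous respiration rate is
#' the analytic-signal frequency of `p(t)`, and the instant respiration
#' modulation converts the phase envelope back to a frequency-deviation
#' amplitude: `B_phi(t) = envelope(p) * RR_phi(t)`.  `B_phi` is reported
#' per harmonic without dividing by the order, so its growth with
#' harmonic order is visible.
#'
#' @inheritParams respiration_from_frequency
#' @param power_floor minimum RMS of the band-passed phase (rad).
#' @return list with `rr`, `mean_rr` (Hz), `b` (instant respiration
#'   modulation series, Hz), `mean_b` (Hz) and `reliable`.
#' @export
respiration_from_phase <- function(track, resp_band = c(0.1, 0.6),
                                   power_floor = 5e-3) {
  stopifnot(inherits(track, "harmonic_track"))
  p <- bandpass_fft(track$phi0, track$fs, resp_band[1], resp_band[2])
  if (sqrt(mean(p^2)) < power_floor)
    return(list(rr = rep(NA_real_, length(p)), mean_rr = NA_real_,
                b = rep(NA_real_, length(p)), mean_b = NA_real_,
                reliable = FALSE))
  s <- resp_if_series(p, track$fs)
  b <- s$env * s$freq
  idx <- central_idx(length(p))
  list(rr = s$freq, mean_rr = mean(s$freq[idx]),
       b = b, mean_b = mean(b[idx]), reliable = TRUE)
}

#' All respiration metrics for one decomposition
#'
#' @param decomp a [assemble()] result.
#' @param resp_band respiratory band, Hz.
#' @return object of class `resp_metrics` with a per-harmonic table of
#'   mean respiration rates (from frequency and from phase) and mean
#'   respiration modulation, plus the instant series.
#' @export
resp_metrics <- function(decomp, resp_band = c(0.1, 0.6)) {
  stopifnot(inherits(decomp, "ppg_decomposition"))
  tracks <- decomp$tracks
  byf <- lapply(tracks, respiration_from_frequency, resp_band = resp_band)
  byp <- lapply(tracks, respiration_from_phase, resp_band = resp_band)
  structure(list(
    per_harmonic = data.frame(
      order = vapply(tracks, function(tr) tr$order, numeric(1)),
      rr_f = vapply(byf, `[[`, numeric(1), "mean_rr"),
      rr_phi = vapply(byp, `[[`, numeric(1), "mean_rr"),
      mean_b_phi = vapply(byp, `[[`, numeric(1), "mean_b"),
      reliable = vapply(byp, `[[`, logical(1), "reliable")),
    rr_f_series = lapply(byf, `[[`, "rr"),
    rr_phi_series = lapply(byp, `[[`, "rr"),
    b_phi_series = lapply(byp, `[[`, "b"),
    resp_band = resp_band),
    class = "resp_metrics")
}

#' @export
print.resp_metrics <- function(x, ...) {
  cat("<resp_metrics>\n")
  print(x$per_harmonic, row.names = FALSE)
  invisible(x)
}
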