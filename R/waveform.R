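# The waveform container: a uniformly sampled real signal with a sampling
# rate and a start time.  All pipeline stages consume and return these.

#' Construct a waveform
#'
#' A `waveform` is the package's carrier for every sampled signal: the raw
#' PPG, baseline drift, the drift-free signal, harmonic components and the
#' reconstructed pulses.
#'
#' @param samples numeric vector of signal values (arbitrary units).
#' @param fs sampling rate in Hz, positive.
#' @param t0 time of the first sample in seconds (default 0).
#' @return an object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 1.2 * (0:999) / 125), fs = 125)
#' print(w)
#' @export
waveform <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (length(samples) < 2L) stop("a waveform needs at least 2 samples")
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = samples, fs = fs, t0 = t0), class = "waveform")
}

is_waveform <- function(x) inherits(x, "waveform")

#' Time axis of a waveform
#' @param w a `waveform`.
#' @return numeric vector of sample times in seconds.
#' @export
wave_time <- function(w) {
  stopifnot(is_waveform(w))
  w$t0 + (seq_along(w$samples) - 1) / w$fs
}

#' Duration of a waveform in seconds
#' @param w a `waveform`.
#' @export
wave_duration <- function(w) length(w$samples) / w$fs

#' Extract a time segment of a waveform
#'
#' Bounds are inclusive at the start and exclusive at the end, in seconds
#' on the waveform's own time axis.
#'
#' @param w a `waveform`.
#' @param start_s,end_s segment bounds in seconds.
#' @return a `waveform` covering `[start_s, end_s)`.
#' @export
segment_waveform <- function(w, start_s, end_s) {
  stopifnot(is_waveform(w), end_s > start_s)
  t <- wave_time(w)
  keep <- which(t >= start_s - 1e-9 & t < end_s - 1e-9)
  if (length(keep) < 2L)
    stop(sprintf("segment [%g, %g) does not fit the record (%g to %g s)",
                 start_s, end_s, t[1], t[length(t)] + 1 / w$fs))
  waveform(w$samples[keep], w$fs, t0 = t[keep[1]])
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz, %.2f s, t0 = %g s\n",
              length(x$samples), x$fs, wave_duration(x), x$t0))
  cat(sprintf("  range [%.4g, %.4g], rms %.4g\n",
              min(x$samples), max(x$samples), sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ..., xlab = "time (s)", ylab = "amplitude (a.u.)",
                          type = "l") {
  graphics::plot(wave_time(x), x$samples, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Internal: assert two waveforms share grid (fs and length, compatible t0).
check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$fs, b$fs)) ||
      length(a$samples) != length(b$samples))
    stop("waveforms must share sampling rate and length")
  invisible(TRUE)
}
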