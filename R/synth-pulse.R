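# Generative model of the true arterial pulse: a sum of heart-rate
# harmonics whose common timing is frequency-modulated by respiration
# (respiratory sinus arrhythmia) and by a non-harmonic "other physiological
# factors" (PF) process.

#' Specify the generative parameters of a true arterial pulse
#'
#' The pulse is
#' \deqn{y(t) = \sum_{i=1}^{N} A_i \cos\Theta_i(t), \qquad
#'   \dot\Theta_i(t)/2\pi = i f_0 + s_i B_i \cos(2\pi f_r t + \alpha_i) + i\,\mathrm{PF}(t)}
#' where \eqn{s_i = i} when `order_scaled = TRUE` (the default: the
#' respiratory frequency deviation of harmonic *i* scales with its order,
#' which is what makes the extracted respiration modulation grow with
#' harmonic order in healthy subjects) and \eqn{s_i = 1} otherwise.
#' PF(t) is a zero-mean Ornstein-Uhlenbeck process with standard deviation
#' `pf_sd` and correlation time `pf_corr_time`; it models the non-harmonic
#' component of heart-rate variability.
#'
#' `B` and `alpha0` may be scalars (one coherent respiratory modulation
#' shared by all harmonics) or length-`N` vectors (per-harmonic amplitude
#' and phase, used by the atrial-fibrillation preset where the harmonics'
#' apparent respiratory modulation is inconsistent).
#'
#' @param f0 fundamental (mean heart-rate) frequency, Hz.
#' @param A harmonic amplitudes, length `N` (a.u., non-negative).
#' @param phi0 harmonic initial phases, rad (recycled to length `N`).
#' @param B respiration-modulation amplitude(s), Hz.
#' @param f_r respiration rate, Hz (`0 <= f_r < f0`).
#' @param alpha0 respiration initial phase(s), rad.
#' @param pf_sd standard deviation of the PF frequency perturbation, Hz.
#' @param pf_corr_time correlation time of the PF process, s.
#' @param order_scaled logical: scale the respiratory deviation of
#'   harmonic *i* by *i*.
#' @return object of class `pulse_spec`.
#' @export
pulse_spec <- function(f0 = 1.2, A = c(1, 0.5, 0.25), phi0 = c(0, 0.9, 0.4),
                       B = 0.03, f_r = 0.25, alpha0 = 0,
                       pf_sd = 0.005, pf_corr_time = 5,
                       order_scaled = TRUE) {
  N <- length(A)
  stopifnot(f0 > 0, N >= 1L, all(A >= 0), all(B >= 0),
            f_r >= 0, f_r < f0, pf_sd >= 0, pf_corr_time > 0)
  structure(list(f0 = f0, N = N, A = as.numeric(A),
                 phi0 = rep_len(as.numeric(phi0), N),
                 B = rep_len(as.numeric(B), N),
                 f_r = f_r,
                 alpha0 = rep_len(as.numeric(alpha0), N),
                 pf_sd = pf_sd, pf_corr_time = pf_corr_time,
                 order_scaled = isTRUE(order_scaled)),
            class = "pulse_spec")
}

#' @export
print.pulse_spec <- function(x, ...) {
  cat(sprintf("<pulse_spec> f0=%.3g Hz (%.0f bpm), %d harmonics\n",
              x$f0, 60 * x$f0, x$N))
  cat(sprintf("  A = %s; B = %s Hz at f_r = %.3g Hz; pf_sd = %.3g Hz (tau %g s)\n",
              paste(signif(x$A, 3), collapse = ", "),
              paste(signif(x$B, 3), collapse = ", "),
              x$f_r, x$pf_sd, x$pf_corr_time))
  invisible(x)
}

# Ornstein-Uhlenbeck process sampled exactly at step 1/fs.
ou_process <- function(n, fs, sd, tau) {
  if (sd == 0) return(numeric(n))
  a <- exp(-1 / (fs * tau))
  z <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- sd * z[1]
  s <- sd * sqrt(1 - a^2)
  for (i in 2:n) x[i] <- a * x[i - 1] + s * z[i]
  x
}

#' Generate a true arterial pulse waveform
#'
#' Accumulates each harmonic's instantaneous frequency by trapezoidal
#' integration at the sampling rate and sums the cosines (see
#' [pulse_spec()] for the model).  The per-harmonic instantaneous
#' frequency and phase used for generation are attached as the
#' `"pulse_truth"` attribute, so downstream estimators can be validated
#' against exact ground truth.
#'
#' @param spec a [pulse_spec()].
#' @param fs sampling rate, Hz; must exceed `4 * N * f0`.
#' @param duration record length, s.
#' @param seed integer seed for the PF process (`NULL` uses the current
#'   RNG stream).
#' @return `waveform` with attribute `pulse_truth`, a list with matrices
#'   `f_inst` and `theta` (columns = harmonics), the `pf` sample path and
#'   the `spec`.
#' @export
make_true_pulse <- function(spec, fs, duration, seed = NULL) {
  stopifnot(inherits(spec, "pulse_spec"), fs > 0, duration > 0)
  if (fs <= 4 * spec$N * spec$f0)
    stop(sprintf(
      "sampling rate %g Hz too low for harmonic %d at %g Hz (need fs > %g)",
      fs, spec$N, spec$N * spec$f0, 4 * spec$N * spec$f0))
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  pf <- with_seed(seed, ou_process(n, fs, spec$pf_sd, spec$pf_corr_time))
  f_inst <- matrix(0, n, spec$N)
  theta <- matrix(0, n, spec$N)
  y <- numeric(n)
  for (i in seq_len(spec$N)) {
    s_i <- if (spec$order_scaled) i else 1
    fi <- i * spec$f0 +
      s_i * spec$B[i] * cos(2 * pi * spec$f_r * t + spec$alpha0[i]) +
      i * pf
    th <- 2 * pi * cumtrapz1(fi, 1 / fs) + spec$phi0[i]
    f_inst[, i] <- fi
    theta[, i] <- th
    y <- y + spec$A[i] * cos(th)
  }
  out <- waveform(y, fs)
  attr(out, "pulse_truth") <- list(f_inst = f_inst, theta = theta,
                                   pf = pf, spec = spec)
  out
}
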