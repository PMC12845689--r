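# The tissue-contact-sensor (TCS) stack as a base-excited mass-spring-damper.
# The true arterial pulse y(t) drives the base; the sensor reads the mass
# displacement x_M(t).  Baseline drift x_b(t) modulates the nominal system
# parameters (time-varying system parameters, TVSP), which turns the stack
# into a slowly time-varying filter and rides multiplicative distortion on
# every pulse harmonic.

#' Configure the SDOF tissue-contact-sensor model
#'
#' Nominal mass/damping/stiffness of the contact stack, the dimensionless
#' coupling of each parameter to baseline drift, the drift generator, and
#' the additive sensor-noise level.  The physical values of `m0`, `c0`,
#' `k0` are not identifiable from a PPG record; the defaults place the
#' stack's natural frequency at 4 Hz with damping ratio 0.3.  A soft
#' tissue-sensor stack resonating just above the analyzed pulse
#' harmonics makes the upper harmonics distinctly sensitive to
#' drift-coupled parameter modulation, reproducing the observed
#' phenomenology of motion artifact in bedside PPG (higher harmonics
#' carry visibly more multiplicative distortion than the fundamental).
#'
#' Parameter coupling is linear in the drift:
#' `m(t) = m0 * (1 + gamma["m"] * x_b(t) / x_b_scale)`, and likewise for
#' `c(t)` and `k(t)`.
#'
#' @param m0 nominal mass (arbitrary consistent units), positive.
#' @param c0 nominal damping, non-negative.  Default critical-damping
#'   ratio 0.3 for the given `m0`, `k0`.
#' @param k0 nominal stiffness, positive.  Default sets the natural
#'   frequency \eqn{\sqrt{k_0/m_0}/2\pi} to 4 Hz.
#' @param gamma named numeric vector `c(m=, c=, k=)` of dimensionless
#'   drift-coupling coefficients.
#' @param x_b_scale drift normalization amplitude (a.u.).
#' @param drift_sins data frame with columns `freq` (Hz, each < 0.7),
#'   `amp` (a.u.) and `phase` (rad): deterministic drift sinusoids.
#' @param drift_walk_amp RMS amplitude (a.u.) of the band-limited random
#'   walk component of the drift, 0 for none.
#' @param noise_sd standard deviation of additive sensor noise (a.u.).
#' @return an object of class `sdof_config`.
#' @seealso [closed_form_gain()], [simulate_tcs()], [make_baseline_drift()]
#' @export
sdof_config <- function(m0 = 1,
                        k0 = (2 * pi * 4)^2 * m0,
                        c0 = 2 * 0.3 * sqrt(k0 * m0),
                        gamma = c(m = 0, c = 0, k = 0),
                        x_b_scale = 1,
                        drift_sins = data.frame(freq = numeric(0),
                                                amp = numeric(0),
                                                phase = numeric(0)),
                        drift_walk_amp = 0,
                        noise_sd = 0) {
  stopifnot(m0 > 0, k0 > 0, c0 >= 0, x_b_scale > 0,
            drift_walk_amp >= 0, noise_sd >= 0)
  gamma <- as.numeric(gamma[c("m", "c", "k")])
  names(gamma) <- c("m", "c", "k")
  if (anyNA(gamma)) stop("gamma must be a named vector with entries m, c, k")
  drift_sins <- as.data.frame(drift_sins)
  if (nrow(drift_sins)) {
    stopifnot(all(c("freq", "amp") %in% names(drift_sins)))
    if (is.null(drift_sins$phase)) drift_sins$phase <- 0
    if (any(drift_sins$freq >= 0.7))
      stop("baseline-drift sinusoid frequencies must be below 0.7 Hz")
    if (any(drift_sins$freq <= 0) || any(drift_sins$amp < 0))
      stop("drift sinusoids need positive frequency and non-negative amplitude")
  }
  structure(list(m0 = m0, c0 = c0, k0 = k0, gamma = gamma,
                 x_b_scale = x_b_scale, drift_sins = drift_sins,
                 drift_walk_amp = drift_walk_amp, noise_sd = noise_sd),
            class = "sdof_config")
}

#' @export
print.sdof_config <- function(x, ...) {
  fn <- sqrt(x$k0 / x$m0) / (2 * pi)
  zeta <- x$c0 / (2 * sqrt(x$k0 * x$m0))
  cat(sprintf("<sdof_config> m0=%g c0=%g k0=%g (fn=%.2f Hz, zeta=%.2f)\n",
              x$m0, x$c0, x$k0, fn, zeta))
  cat(sprintf("  gamma m/c/k = %g/%g/%g, x_b_scale=%g, walk=%g, noise_sd=%g\n",
              x$gamma["m"], x$gamma["c"], x$gamma["k"], x$x_b_scale,
              x$drift_walk_amp, x$noise_sd))
  if (nrow(x$drift_sins))
    cat(sprintf("  drift sinusoids: %s\n",
                paste(sprintf("%.3g Hz x %.3g", x$drift_sins$freq,
                              x$drift_sins$amp), collapse = ", ")))
  invisible(x)
}

#' Closed-form gain and phase of the artifact-free contact stack
#'
#' For constant parameters the base-excited stack acts as the linear filter
#' \deqn{H(j\omega) = \frac{k_0 + j c_0 \omega}{k_0 - m_0\omega^2 + j c_0 \omega},}
#' so a harmonic input at angular frequency `omega_y` reaches the sensor
#' scaled by `G0 = |H|` and shifted by `phi0_shift = arg(H)`.
#'
#' @param m0,c0,k0 constant system parameters (`m0`, `k0` positive,
#'   `c0` non-negative).
#' @param omega_y angular frequency of the input, rad/s, non-negative.
#' @return list with elements `G0` (gain) and `phi0_shift` (rad, in
#'   \eqn{(-\pi, \pi]}).
#' @examples
#' closed_form_gain(1, 0.5, 100, 2 * pi * 1.2)
#' @export
closed_form_gain <- function(m0, c0, k0, omega_y) {
  stopifnot(m0 >= 0, k0 > 0, c0 >= 0, all(omega_y >= 0))
  if (c0 == 0 && any(abs(omega_y - sqrt(k0 / max(m0, .Machine$double.xmin)))
                     < 1e-12 * sqrt(k0)))
    stop("undamped resonance: c0 = 0 and omega_y = sqrt(k0/m0) is singular")
  num <- complex(real = k0, imaginary = c0 * omega_y)
  den <- complex(real = k0 - m0 * omega_y^2, imaginary = c0 * omega_y)
  H <- num / den
  list(G0 = Mod(H), phi0_shift = wrap_pi(Arg(H)))
}

#' Simulate the contact stack's response to a pulse under drift coupling
#'
#' Integrates
#' \deqn{m(t)\,\ddot{x}_M + c(t)\,\dot{x}_M + k(t)\,x_M = k(t)\,y + c(t)\,\dot{y}}
#' with `m(t)`, `c(t)`, `k(t)` linearly coupled to the supplied baseline
#' drift (see [sdof_config()]).  Integration is classical fixed-step
#' fourth-order Runge-Kutta at the signal sampling rate; the forcing and
#' the parameter tracks are interpolated linearly at half steps.  `y`'s
#' derivative is formed by fourth-order central differences.
#'
#' Initial conditions are `x_M(0) = y(0) * G0` (steady-state estimate at
#' the input's dominant frequency) and zero velocity; the start-up
#' transient is flagged via the `"transient_s"` attribute (5 s).
#'
#' @param y true pulse `waveform` (base excitation).
#' @param x_b baseline-drift `waveform` on the same grid (drives the TVSP
#'   coupling only; it is *not* added to the output).
#' @param sdof an [sdof_config()].
#' @return `waveform` of the mass displacement `x_M`, with attribute
#'   `transient_s = 5`.
#' @export
simulate_tcs <- function(y, x_b, sdof) {
  stopifnot(is_waveform(y), is_waveform(x_b), inherits(sdof, "sdof_config"))
  check_same_grid(y, x_b)
  fs <- y$fs
  h <- 1 / fs
  ys <- y$samples
  n <- length(ys)
  g <- sdof$gamma
  mod <- x_b$samples / sdof$x_b_scale
  m <- sdof$m0 * (1 + g["m"] * mod)
  cc <- sdof$c0 * (1 + g["c"] * mod)
  k <- sdof$k0 * (1 + g["k"] * mod)
  if (min(m) <= 0 || min(k) <= 0)
    stop("TVSP instability: m(t) or k(t) became non-positive; ",
         "reduce gamma or the drift amplitude")
  if (any(cc < 0))
    stop("TVSP instability: c(t) became negative")
  FF <- k * ys + cc * gradient4(ys, h)

  # steady-state-ish initial displacement at the input's dominant frequency
  G0 <- 1
  if (any(ys != 0)) {
    pk <- try(spec_peak(ys, fs, c(0.1, fs / 4)), silent = TRUE)
    if (!inherits(pk, "try-error") && pk$prominence > 20)
      G0 <- closed_form_gain(sdof$m0, sdof$c0, sdof$k0, 2 * pi * pk$freq)$G0
  }

  x <- numeric(n)
  x[1] <- ys[1] * G0
  v <- 0
  for (i in seq_len(n - 1L)) {
    Fa <- FF[i]; Fb <- FF[i + 1L]; Fm <- (Fa + Fb) / 2
    ma <- m[i];  mb <- m[i + 1L];  mm <- (ma + mb) / 2
    ca <- cc[i]; cb <- cc[i + 1L]; cm <- (ca + cb) / 2
    ka <- k[i];  kb <- k[i + 1L];  km <- (ka + kb) / 2
    xi <- x[i]
    k1x <- v
    k1v <- (Fa - ca * v - ka * xi) / ma
    x2 <- xi + h / 2 * k1x; v2 <- v + h / 2 * k1v
    k2x <- v2
    k2v <- (Fm - cm * v2 - km * x2) / mm
    x3 <- xi + h / 2 * k2x; v3 <- v + h / 2 * k2v
    k3x <- v3
    k3v <- (Fm - cm * v3 - km * x3) / mm
    x4 <- xi + h * k3x; v4 <- v + h * k3v
    k4x <- v4
    k4v <- (Fb - cb * v4 - kb * x4) / mb
    x[i + 1L] <- xi + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    v <- v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    if (!is.finite(x[i + 1L]) || !is.finite(v))
      stop("integration diverged at t = ", format(i * h, digits = 4), " s")
  }
  out <- waveform(x, fs, t0 = y$t0)
  attr(out, "transient_s") <- 5
  out
}
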