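# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard clean pulse: 3 harmonics, small coherent respiratory FM,
# no PF process.
clean_spec <- function(f0 = 1.2, B = 0.03, f_r = 0.25, pf_sd = 0) {
  pulse_spec(f0 = f0, A = c(1, 0.5, 0.25), phi0 = c(0, 0.9, 0.4),
             B = B, f_r = f_r, alpha0 = 0.4, pf_sd = pf_sd)
}

# Artifact-free contact stack (no drift, no coupling, no noise).
clean_sdof <- function() sdof_config()

# The standing non-AF study conditions with artifact and noise on.
default_ma_sdof <- function() {
  sdof_config(gamma = c(m = 0.05, c = 0.10, k = 0.15),
              drift_sins = data.frame(freq = c(0.08, 0.25),
                                      amp = c(0.12, 0.04),
                                      phase = c(0.5, 1.1)),
              drift_walk_amp = 0.03, noise_sd = 0.01)
}

# Strong TVSP with no physiological frequency modulation: isolates the
# artifact's effect on the instant parameters.  The drift is
# breathing-dominated (contact-pressure modulation by respiration), the
# canonical motion source in an at-rest recording.
tvsp_only_record <- function(seed = 11) {
  spec <- pulse_spec(f0 = 1.2, A = c(1, 0.5, 0.25), phi0 = c(0, 0.9, 0.4),
                     B = 0, f_r = 0.25, pf_sd = 0)
  sdof <- sdof_config(gamma = c(m = 0.10, c = 0.25, k = 0.35),
                      drift_sins = data.frame(freq = c(0.28, 0.10),
                                              amp = c(0.35, 0.10),
                                              phase = c(0.3, 2.1)),
                      drift_walk_amp = 0.05, noise_sd = 0)
  make_ppg(spec, sdof, seed = seed)
}

# Independent periodogram oracle (plain base-R FFT, rectangular window).
oracle_power_fraction <- function(x, fs, f_lo = -Inf, f_hi = Inf) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(stats::fft(x)[2:floor(n / 2)])^2
  f <- (1:(floor(n / 2) - 1)) * fs / n
  sum(P[f >= f_lo & f <= f_hi]) / sum(P)
}

# Independent circular-mean oracle.
oracle_circular_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta)))
}

# Analyze one synthetic record with the standard segment.
fit_record <- function(rec, ...) {
  sdof_tf(rec, segment = c(5, wave_duration(rec$ppg)), ...)
}
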