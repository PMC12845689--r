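test_that("amplitude trend is an ordinary least-squares line", {
  fs <- 125
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  fake <- structure(list(t = t, A = rep(0.5, length(t)), fs = fs),
                    class = "harmonic_track")
  expect_equal(amplitude_trend(fake), rep(0.5, length(t)))

  fake$A <- 0.5 + 0.01 * t
  expect_equal(amplitude_trend(fake), fake$A, tolerance = 1e-10)

  # line plus a zero-mean swing: the fit recovers the line (lm oracle)
  swing <- 0.2 * cos(2 * pi * 0.1 * t + 0.3)
  fake$A <- 0.5 + 0.01 * t + swing
  line <- 0.5 + 0.01 * t
  oracle <- unname(stats::lm(fake$A ~ t)$fitted.values)
  est <- amplitude_trend(fake)
  expect_equal(est, oracle, tolerance = 1e-9)
  expect_lt(max(abs(est - line)) / mean(line), 0.02)
})

test_that("phase mean is circular-safe", {
  expect_equal(phase_mean(rep(0.3, 100)), 0.3)
  t <- seq(0, 10, by = 0.01)
  expect_equal(phase_mean(0.3 + 0.5 * sin(2 * pi * t)), 0.3,
               tolerance = 0.01)
  # sequence straddling the branch cut
  set.seed(5)
  th <- pi - 0.05 + 0.2 * runif(500)        # wraps past +pi
  wrapped <- atan2(sin(th), cos(th))
  expect_equal(phase_mean(wrapped), oracle_circular_mean(wrapped),
               tolerance = 1e-6)
})

test_that("with nothing to remove, x_tf stays close to x_HVD", {
  rec <- make_ppg(clean_spec(), clean_sdof(), seed = 31)
  fit <- fit_record(rec)
  r <- fit$reconstruction
  d <- fit$decomposition
  rel <- sqrt(mean((r$x_tf$samples - d$x_HVD$samples)^2)) /
    sqrt(mean(d$x_HVD$samples^2))
  expect_lt(rel, 0.02)
  # definitional identity
  expect_true(all(r$x_tvsp$samples ==
                    d$x_HVD$samples - r$x_tf$samples))
})

test_that("artifact removal moves the reconstruction toward the true pulse", {
  rec <- tvsp_only_record(seed = 33)
  fit <- fit_record(rec)
  idx <- round(wave_time(fit$reconstruction$x_tf) * 125) + 1L
  x_C <- rec$truth$x_C$samples[idx]
  c_tf <- stats::cor(fit$reconstruction$x_tf$samples, x_C)
  c_hvd <- stats::cor(fit$decomposition$x_HVD$samples, x_C)
  expect_gt(c_tf, c_hvd)
})

test_that("TVSP energy is an order of magnitude lower without coupling", {
  # matched spec and drift; only the parameter coupling differs
  spec <- pulse_spec(f0 = 1.2, A = c(1, 0.5, 0.25), phi0 = c(0, 0.9, 0.4),
                     B = 0, f_r = 0.25, pf_sd = 0)
  drift <- data.frame(freq = c(0.06, 0.22), amp = c(0.35, 0.12),
                      phase = c(0.3, 2.1))
  rec_off <- make_ppg(spec, sdof_config(drift_sins = drift,
                                        drift_walk_amp = 0.08), seed = 11)
  rec_on <- tvsp_only_record(seed = 11)
  rms_tvsp <- function(rec) {
    fit <- fit_record(rec)
    v <- fit$reconstruction$x_tvsp$samples
    n <- length(v)
    sqrt(mean(v[round(0.1 * n):round(0.9 * n)]^2))  # settled interior
  }
  expect_lt(rms_tvsp(rec_off), 0.05 * rms_tvsp(rec_on))
})

test_that("zero-HRV records make the two reconstructions coincide", {
  rec <- make_ppg(pulse_spec(B = 0, pf_sd = 0), clean_sdof(), seed = 35)
  fit <- fit_record(rec)
  r <- fit$reconstruction
  rel <- sqrt(mean((r$x_cf$samples - r$x_tf$samples)^2)) /
    sqrt(mean(r$x_tf$samples^2))
  expect_lt(rel, 0.01)
})

test_that("a single harmonic reconstructs as an envelope-scaled cosine", {
  fs <- 125
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tr <- hvd_track(waveform((1 + 0.002 * t) * cos(2 * pi * 1.2 * t), fs), 1)
  cf <- reconstruct_cf(list(tr))
  env <- amplitude_trend(tr)
  # the constant-frequency reconstruction's envelope is the fitted line
  # (judged away from the analytic-signal end effects)
  idx <- 500:(length(cf$samples) - 500)
  expect_lt(max(abs(Mod(analytic_signal(cf$samples))[idx] -
                      env[idx])) / mean(env), 0.02)
})

test_that("x_tf and x_cf agree in harmonic peak magnitude", {
  rec <- make_ppg(clean_spec(), default_ma_sdof(), seed = 37)
  fit <- fit_record(rec)
  r <- fit$reconstruction
  n <- length(r$x_tf$samples)
  f <- (0:(n - 1)) * 125 / n
  for (i in 1:3) {
    # FM spreads x_tf's line into sidebands; equal envelopes mean equal
    # energy within the harmonic's band
    band <- abs(f - i * fit$f0_est) < 0.45 * fit$f0_est
    e_tf <- sqrt(sum(Mod(stats::fft(r$x_tf$samples))[band]^2))
    e_cf <- sqrt(sum(Mod(stats::fft(r$x_cf$samples))[band]^2))
    expect_equal(e_tf / e_cf, 1, tolerance = 0.02)
  }
})

test_that("pulse-waveform features recover amplitude ratios and phases", {
  fake_tracks <- lapply(1:3, function(i) {
    t <- seq(0, 60, by = 1 / 125)
    structure(list(order = i, t = t, A = rep(1, length(t)),
                   phi0 = rep(c(0, 0.2, 0.5)[i], length(t)), fs = 125),
              class = "harmonic_track")
  })
  A_tilde <- lapply(fake_tracks, amplitude_trend)
  phi_bar <- vapply(fake_tracks, phase_mean, numeric(1))
  f <- sdoftf:::apw_features_internal(A_tilde, phi_bar, 1:3)
  expect_equal(unname(f$amp_ratio), c(1, 1))
  expect_equal(unname(f$phase_diff), c(0.2, 0.5), tolerance = 1e-9)
  expect_true(f$phase_flag)

  # known-truth recovery through the full chain (artifact-free record,
  # compensating the contact stack's mild gain at each harmonic)
  rec <- make_ppg(clean_spec(), clean_sdof(), seed = 39)
  fit <- fit_record(rec)
  g <- vapply(1:3, function(i)
    closed_form_gain(1, sdof_config()$c0, sdof_config()$k0,
                     2 * pi * i * 1.2)$G0, numeric(1))
  expected <- c(0.5, 0.25) * g[2:3] / g[1]
  expect_equal(unname(fit$reconstruction$amp_ratio), expected,
               tolerance = 0.05)
})

test_that("HRV distorts the AF pulse shape far more than the non-AF one", {
  co <- generate_cohort(1, 1, seed = 19)
  dis <- vapply(co, function(r) {
    fit <- fit_record(r)
    sqrt(mean((fit$reconstruction$x_cf$samples -
                 fit$reconstruction$x_tf$samples)^2)) /
      sqrt(mean(fit$reconstruction$x_tf$samples^2))
  }, numeric(1))
  expect_gt(dis[1], 3 * dis[2])   # AF first in the cohort
})
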