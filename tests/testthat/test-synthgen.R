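test_that("a degenerate single-harmonic spec yields a pure cosine", {
  spec <- pulse_spec(f0 = 1.2, A = 1, phi0 = 0, B = 0, pf_sd = 0)
  y <- make_true_pulse(spec, fs = 125, duration = 20)
  t <- wave_time(y)
  expect_equal(y$samples, cos(2 * pi * 1.2 * t), tolerance = 1e-9)
  truth <- attr(y, "pulse_truth")
  expect_true(all(abs(truth$f_inst[, 1] - 1.2) < 1e-12))
})

test_that("respiratory FM advances the phase exactly as its integral", {
  # zero-crossing count of harmonic 1 over 80 s vs an oracle integrating
  # the stated instantaneous frequency in closed form
  B <- 0.05; f_r <- 0.25; f0 <- 1.2; a0 <- 0.7; T <- 80
  spec <- pulse_spec(f0 = f0, A = 1, phi0 = 0, B = B, f_r = f_r,
                     alpha0 = a0, pf_sd = 0)
  y <- make_true_pulse(spec, fs = 125, duration = T)
  crossings <- sum(diff(sign(y$samples)) != 0)
  cycles_oracle <- f0 * T +
    B / (2 * pi * f_r) * (sin(2 * pi * f_r * T + a0) - sin(a0))
  expect_lt(abs(crossings - 2 * cycles_oracle), 2)
})

test_that("Nyquist violations name the offending harmonic", {
  spec <- pulse_spec(f0 = 1.2, A = c(1, 0.5, 0.25))
  expect_error(make_true_pulse(spec, fs = 12, duration = 10), "harmonic 3")
})

test_that("baseline drift is reproducible, band-limited, and validated", {
  sdof0 <- sdof_config()
  xb0 <- make_baseline_drift(sdof0, 125, 80, seed = 3)
  expect_true(all(xb0$samples == 0))          # null drift

  sdof1 <- sdof_config(drift_sins = data.frame(freq = 0.1, amp = 1,
                                               phase = 0))
  xb1 <- make_baseline_drift(sdof1, 125, 80, seed = 3)
  # periodogram oracle: peak bin at 0.1 Hz, out-of-band power < 1%
  n <- length(xb1$samples)
  P <- Mod(stats::fft(xb1$samples - mean(xb1$samples))[2:(n / 2)])^2
  f <- (1:(n / 2 - 1)) * 125 / n
  expect_equal(f[which.max(P)], 0.1, tolerance = 0.01)
  expect_lt(1 - oracle_power_fraction(xb1$samples, 125, 0.05, 0.15), 0.01)

  sdof2 <- sdof_config(drift_sins = data.frame(freq = c(0.08, 0.3),
                                               amp = c(0.4, 0.1),
                                               phase = c(0, 1)),
                       drift_walk_amp = 0.1)
  xb2 <- make_baseline_drift(sdof2, 125, 80, seed = 5)
  expect_gt(oracle_power_fraction(xb2$samples, 125, 0, 0.7), 0.99)
  expect_identical(xb2$samples,
                   make_baseline_drift(sdof2, 125, 80, seed = 5)$samples)

  expect_error(sdof_config(drift_sins = data.frame(freq = 0.8, amp = 1)),
               "below 0.7")
})

test_that("record composition identities hold", {
  rec <- make_ppg(clean_spec(), default_ma_sdof(), seed = 9)
  lhs <- rec$ppg$samples - rec$truth$x_b$samples - rec$truth$x_noise_true$samples
  rel <- max(abs(lhs - rec$truth$x_M$samples)) / max(abs(rec$truth$x_M$samples))
  expect_lt(rel, 1e-9)

  # artifact-free record: no TVSP distortion, PPG equals the mass response
  rec0 <- make_ppg(clean_spec(), clean_sdof(), seed = 9)
  expect_true(all(rec0$truth$x_tvsp_true$samples == 0))
  expect_equal(rec0$ppg$samples, rec0$truth$x_M$samples, tolerance = 1e-12)
})

test_that("records are bit-reproducible from their seed", {
  a <- make_ppg(clean_spec(pf_sd = 0.01), default_ma_sdof(), seed = 77)
  b <- make_ppg(clean_spec(pf_sd = 0.01), default_ma_sdof(), seed = 77)
  expect_identical(a$ppg$samples, b$ppg$samples)
  c <- make_ppg(clean_spec(pf_sd = 0.01), default_ma_sdof(), seed = 78)
  expect_false(identical(a$ppg$samples, c$ppg$samples))
})

test_that("cohort generation books labels, counts and determinism", {
  expect_identical(generate_cohort(0, 0, seed = 1), list())
  co <- generate_cohort(3, 2, preset_overrides = list(duration = 40),
                        seed = 42)
  expect_length(co, 5L)
  labs <- vapply(co, function(r) r$truth$label, character(1))
  expect_identical(labs, c("AF", "AF", "AF", "non-AF", "non-AF"))
  co2 <- generate_cohort(3, 2, preset_overrides = list(duration = 40),
                         seed = 42)
  for (j in seq_along(co))
    expect_identical(co[[j]]$ppg$samples, co2[[j]]$ppg$samples)
})

test_that("AF preset drift amplitude is a third to a half of the pulse", {
  co <- generate_cohort(3, 0, preset_overrides = list(duration = 40),
                        seed = 8)
  for (r in co) {
    pulse_amp <- max(abs(r$truth$x_M$samples))
    drift_amp <- max(abs(r$truth$x_b$samples))
    expect_gt(drift_amp / pulse_amp, 0.2)
    expect_lt(drift_amp / pulse_amp, 0.8)
  }
})
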