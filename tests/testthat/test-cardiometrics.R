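fake_track <- function(f, i = 1, fs = 125, phi0 = NULL, f_mean = mean(f)) {
  n <- length(f)
  structure(list(order = i, t = (0:(n - 1)) / fs, A = rep(1, n), f = f,
                 phi0 = phi0 %||% rep(0, n), fs = fs, f_mean = f_mean),
            class = "harmonic_track")
}

test_that("heart rate from instant frequency is order-normalized", {
  n <- 8000
  tr <- fake_track(rep(2.4, n), i = 2)
  h <- hr_from_frequency(tr)
  expect_true(all(h$hr == 72))
  expect_equal(h$rmse_hr, 0)

  t <- (0:(n - 1)) / 125
  tr2 <- fake_track(1.2 + 0.05 * cos(2 * pi * 0.25 * t), i = 1)
  h2 <- hr_from_frequency(tr2)
  # RMS of a sinusoid: 60 * 0.05 / sqrt(2) = 2.121 bpm
  expect_equal(h2$rmse_hr, 60 * 0.05 / sqrt(2), tolerance = 0.01)
})

test_that("subject heart rate summarizes across harmonics", {
  n <- 1000
  trs <- list(fake_track(rep(71 / 60, n), 1),
              fake_track(rep(2 * 72 / 60, n), 2),
              fake_track(rep(3 * 73 / 60, n), 3))
  s <- hr_summary(trs)
  expect_equal(s$HR, 72)
  expect_equal(s$SD_HR, 1)
  same <- list(fake_track(rep(1.2, n), 1), fake_track(rep(2.4, n), 2))
  expect_equal(hr_summary(same)$SD_HR, 0)
})

test_that("phase-derived heart rate obeys the FM identity", {
  fs <- 125
  n <- 80 * fs
  t <- (0:(n - 1)) / fs
  phi0 <- (0.05 / 0.25) * sin(2 * pi * 0.25 * t)
  tr <- fake_track(rep(1.2, n), i = 1, phi0 = phi0, f_mean = 1.2)
  h <- hr_from_phase(tr)
  expect_true(h$reliable)
  mid <- 2000:8000
  expect_equal(max(h$hr[mid]), 75, tolerance = 0.01)
  expect_equal(min(h$hr[mid]), 69, tolerance = 0.01)
  expect_equal(h$rmse_hr, 3 / sqrt(2), tolerance = 0.05)

  trc <- fake_track(rep(1.2, n), i = 1, phi0 = rep(0.4, n), f_mean = 1.2)
  hc <- hr_from_phase(trc)
  expect_false(hc$reliable)
  expect_true(all(hc$hr == 72))
  expect_equal(hc$rmse_hr, 0)

  s <- hr_phase_summary(list(tr, fake_track(rep(2.4, n), i = 2,
                                            phi0 = 2 * phi0, f_mean = 2.4)))
  expect_equal(s$HR_phi, 72, tolerance = 0.01)
  expect_lt(s$SD_HR_phi, 0.05)
})

test_that("cycle segmentation counts beats and reproduces beat times", {
  fs <- 125
  t <- seq(0, 80 - 1 / fs, by = 1 / fs)
  seg <- segment_cycles(waveform(cos(2 * pi * 1.2 * t), fs), 1.2)
  expect_equal(length(seg$onsets), 96, tolerance = 1)

  expect_error(segment_cycles(waveform(rep(1, 1000), fs), 1.2),
               "flat|cycles")

  # known-truth beat times: intervals between onsets of the true first
  # harmonic match the generator's per-beat periods within 1 sample RMS
  spec <- clean_spec(pf_sd = 0.01)
  rec <- make_ppg(spec, clean_sdof(), seed = 44)
  truth <- rec$truth$pulse_truth
  w1 <- waveform(cos(truth$theta[, 1]), 125)
  seg1 <- segment_cycles(w1, 1.2)
  # oracle: times at which the true phase crosses the onset phase (mod 2pi)
  th <- truth$theta[, 1]
  tt <- wave_time(w1)
  ph_on <- th[seg1$onsets[1]]
  ks <- seq(0, floor((th[length(th)] - ph_on) / (2 * pi)))
  oracle_times <- stats::approx(th, tt, xout = ph_on + 2 * pi * ks)$y
  oracle_times <- oracle_times[oracle_times >= min(seg1$times) - 0.01 &
                                 oracle_times <= max(seg1$times) + 0.01]
  m <- min(length(oracle_times), length(seg1$times))
  err <- diff(seg1$times[1:m]) - diff(oracle_times[1:m])
  expect_lt(sqrt(mean(err^2)), 1 / 125)
})

test_that("RMSSD matches its defining formula", {
  expect_equal(rmssd(rep(72, 10)), 0)
  expect_equal(rmssd(c(71, 73, 71, 73)), 2)
  set.seed(3)
  hr <- 70 + rnorm(50)
  expect_equal(rmssd(hr), sqrt(mean(diff(hr)^2)), tolerance = 1e-12)
  expect_error(rmssd(c(70, 71)), "3 cycles")
})

test_that("clean records recover the generator's rates and variability", {
  spec <- clean_spec()        # B = 0.03, pf_sd = 0
  rec <- make_ppg(spec, clean_sdof(), seed = 47)
  fit <- fit_record(rec)
  expect_equal(fit$cardiac$HR, 72, tolerance = 0.2)
  expect_lt(fit$cardiac$SD_HR, 0.05)
  # RMSE of harmonic 1's HR: 60*sqrt(B^2/2 + pf_sd^2)
  pred <- 60 * sqrt(spec$B[1]^2 / 2 + spec$pf_sd^2)
  expect_equal(unname(fit$indices$rmse_hr["h1"]), pred, tolerance = 0.15 * pred)
  # time-domain HR from the first harmonic agrees with the TF estimate
  expect_equal(mean(fit$cardiac$td$x1$hr), fit$cardiac$HR, tolerance = 1)
})

test_that("across-harmonic HR spread shrinks as variability sources vanish", {
  # averaged over a few records: at the lowest variability SD_HR is at the
  # estimator's numerical floor and single records can tie
  sds <- vapply(c(0.15, 0.05, 0.005), function(pf) {
    mean(vapply(50:52, function(s) {
      rec <- make_ppg(clean_spec(pf_sd = pf), default_ma_sdof(), seed = s)
      suppressWarnings(fit_record(rec)$cardiac$SD_HR)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})
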