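test_that("closed-form gain matches limits and a direct complex oracle", {
  # static limit: zero frequency passes unchanged
  g <- closed_form_gain(1, 0.5, 100, 0)
  expect_equal(g$G0, 1)
  expect_equal(g$phi0_shift, 0)

  # massless stack: numerator equals denominator at every frequency
  for (w in c(0.5, 3, 40)) {
    g <- closed_form_gain(0, 2, 50, w)
    expect_equal(g$G0, 1)
    expect_equal(g$phi0_shift, 0)
  }

  # independent complex-arithmetic oracle
  m0 <- 1; c0 <- 0.5; k0 <- 100
  for (f in c(0.7, 1.2, 2.4)) {
    w <- 2 * pi * f
    H <- complex(real = k0, imaginary = c0 * w) /
      complex(real = k0 - m0 * w^2, imaginary = c0 * w)
    g <- closed_form_gain(m0, c0, k0, w)
    expect_equal(g$G0, Mod(H), tolerance = 1e-12)
    expect_equal(g$phi0_shift, Arg(H), tolerance = 1e-12)
  }

  # undamped resonance is singular
  expect_error(closed_form_gain(1, 0, 100, 10), "resonance")
})

test_that("constant-parameter simulation reproduces the closed form", {
  sdof <- sdof_config()
  fs <- 125
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  f <- 1.7
  w <- 2 * pi * f
  y <- waveform(cos(w * t), fs)
  xb <- waveform(numeric(length(t)), fs)
  xm <- simulate_tcs(y, xb, sdof)
  keep <- t > 5
  X <- cbind(cos(w * t[keep]), sin(w * t[keep]))
  cf <- qr.solve(X, xm$samples[keep])
  ref <- closed_form_gain(sdof$m0, sdof$c0, sdof$k0, w)
  expect_equal(sqrt(sum(cf^2)), ref$G0, tolerance = 0.01)
  expect_equal(atan2(-cf[2], cf[1]), ref$phi0_shift, tolerance = 0.02)
})

test_that("zero input yields zero output even under drift coupling", {
  fs <- 125
  n <- 1250
  y <- waveform(numeric(n), fs)
  xb <- waveform(0.3 * sin(2 * pi * 0.1 * (0:(n - 1)) / fs), fs)
  sdof <- sdof_config(gamma = c(m = 0.1, c = 0.2, k = 0.3))
  xm <- simulate_tcs(y, xb, sdof)
  expect_true(all(xm$samples == 0))
})

test_that("step response follows the analytic damped oscillator", {
  # soft stack so the discretized base-velocity impulse is well resolved
  m0 <- 1; fn <- 2; k0 <- (2 * pi * fn)^2; zeta <- 0.2
  c0 <- 2 * zeta * sqrt(k0 * m0)
  sdof <- sdof_config(m0 = m0, k0 = k0, c0 = c0)
  fs <- 125
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  y <- waveform(as.numeric(t >= 1), fs)
  xb <- waveform(numeric(length(t)), fs)
  xm <- simulate_tcs(y, xb, sdof)

  a <- zeta * sqrt(k0 / m0)
  wd <- sqrt(k0 / m0) * sqrt(1 - zeta^2)
  ts <- pmax(t - 1, 0)
  x_ref <- ifelse(t >= 1,
                  1 - exp(-a * ts) * (cos(wd * ts) - (a / wd) * sin(wd * ts)),
                  0)
  # compare the settling envelopes: ring-down extrema of simulation and
  # analytic response (insensitive to sub-sample timing of the step)
  extrema <- function(x, keep) {
    d <- diff(sign(diff(x)))
    i <- which(d != 0) + 1L
    i <- i[keep[i]]
    abs(x[i] - 1)
  }
  keep <- t >= 1.05 & t <= 3
  e_sim <- extrema(xm$samples, keep)
  e_ref <- extrema(x_ref, keep)
  m <- min(length(e_sim), length(e_ref))
  expect_lt(max(abs(e_sim[1:m] - e_ref[1:m])), 0.02)
})

test_that("TVSP coupling that drives parameters non-positive is rejected", {
  fs <- 125
  n <- 1250
  y <- waveform(cos(2 * pi * 1.2 * (0:(n - 1)) / fs), fs)
  xb <- waveform(rep(1.0, n) + 0.001 * sin(2 * pi * 0.1 * (0:(n - 1)) / fs),
                 fs)
  sdof <- sdof_config(gamma = c(m = 0, c = 0, k = -1.5))
  expect_error(simulate_tcs(y, xb, sdof), "instability")
})
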