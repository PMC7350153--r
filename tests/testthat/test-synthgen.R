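test_that("generation is deterministic, zero-amplitude specs give silence, and invalid specs are rejected", {
  s <- synth_spec("gam", duration = 5, sampling_rate = 1000, seed = 1)
  a <- gen_recording(s)
  b <- gen_recording(s)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$events, b$truth$events)

  z <- gen_recording(synth_spec("gam", duration = 2, sampling_rate = 1000,
                                gamma_amp = 0, noise_amp = 0, burst_rate = 0))
  expect_true(all(z$recording$data == 0))

  expect_error(synth_spec("gam", duration = -1), "duration")
  expect_error(synth_spec("nonsense"), "arg")
  expect_error(synth_spec("gam", theta_mod_depth = 1.5), "theta_mod_depth")
  expect_error(synth_spec("gam", gamma_freq = 40, sampling_rate = 100),
               "sampling_rate")
  expect_error(synth_spec("spwr", ripple_freq = 200, sampling_rate = 500),
               "sampling_rate")
})

test_that("sharp wave-ripple event counts follow the Poisson expectation and exponential interval law", {
  # rate 12/min over 600 s: expected ~120 events, Poisson 3-sigma band
  s <- synth_spec("spwr", duration = 600, sampling_rate = 1000,
                  ripple_freq = 200, spwr_rate = 12, seed = 42)
  g <- gen_recording(s)
  n <- nrow(g$truth$events)
  expect_lt(abs(n - 120), 3 * sqrt(120))
  expect_true(all(diff(g$truth$events$time_s) > 0))
  expect_true(all(g$truth$events$time_s >= 0 & g$truth$events$time_s <= 600))

  # inter-event intervals consistent with an exponential at the nominal rate
  iv <- diff(g$truth$events$time_s)
  ks <- suppressWarnings(stats::ks.test(iv, "pexp", rate = 12 / 60))
  expect_gt(ks$p.value, 0.01)
})

test_that("theta-gamma modulation imprints the theta-phase waveform on the gamma envelope", {
  s <- synth_spec("thegam", duration = 30, sampling_rate = 1000,
                  theta_mod_depth = 1, noise_amp = 0, amp_mod_cv = 0,
                  freq_jitter_sd = 0, seed = 3)
  g <- gen_recording(s)
  x <- g$recording$data[, 1]
  fs <- g$recording$fs
  xf <- slicemetrics:::zp_filter(x, fs, low = 30, high = 70)
  env <- slicemetrics:::hilbert_envelope(xf)
  t <- (seq_along(x) - 1) / fs
  mod <- (1 + cos(2 * pi * s$theta_freq * t)) / 2
  keep <- seq(round(fs), length(x) - round(fs))  # drop filter edges
  expect_gt(stats::cor(env[keep], mod[keep]), 0.9)
})

test_that("two-channel recordings embed the CA3->CA1 lag and share noise as configured", {
  s <- synth_spec("gam", duration = 20, sampling_rate = 1000, n_channels = 2,
                  channel_lag = 10, channel_noise_corr = 1, seed = 4)
  g <- gen_recording(s)
  expect_identical(g$recording$channels, c("ca3_uV", "ca1_uV"))
  lag_n <- round(10 / 1000 * 1000)
  n <- g$recording$n
  # with fully shared noise channel 2 is an exact delayed copy
  expect_equal(g$recording$data[seq_len(n - lag_n), 1],
               g$recording$data[(lag_n + 1):n, 2], tolerance = 1e-12)
})

test_that("synthetic oxygen profiles reproduce the forward model plus calibrated noise", {
  m <- oxygen_model(Vmax = 0.05)
  grid <- seq(0, 400, by = 2)

  p0 <- gen_oxygen_profile(m, grid, noise_sd = 0, seed = 1)
  fwd <- forward_profile(m)
  expect_equal(p0$concentration,
               stats::spline(fwd$depth, fwd$concentration, xout = grid)$y,
               tolerance = 1e-12)

  # no consumption, equal boundaries -> flat at the far-field concentration
  flat <- gen_oxygen_profile(oxygen_model(Vmax = 0, C_bottom = 1), grid, 0)
  expect_equal(flat$concentration, rep(1, length(grid)), tolerance = 1e-9)

  # generated noise has the configured scale (>= 200 grid points)
  pn <- gen_oxygen_profile(m, grid, noise_sd = 0.02, seed = 14)
  res <- pn$concentration - p0$concentration
  expect_lt(abs(stats::sd(res) - 0.02) / 0.02, 0.2)

  expect_error(gen_oxygen_profile(m, c(-5, 0, 10), 0), "within")
  expect_error(gen_oxygen_profile(m, c(0, 450), 0), "within")
})
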