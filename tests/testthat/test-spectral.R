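test_that("Morlet spectrogram localizes a pure tone and respects its contracts", {
  rec <- sine_recording(40, fs = 1000, duration = 10)
  sp <- wavelet_spectrogram(rec, fmin = 20, fmax = 80)
  expect_s3_class(sp, "spectrogram")
  expect_true(all(sp$power >= 0))
  expect_true(!is.unsorted(sp$freqs, strictly = TRUE) &&
                !is.unsorted(sp$times, strictly = TRUE))
  avg <- rowMeans(sp$power)
  step <- sp$freqs[2] - sp$freqs[1]
  expect_lte(abs(sp$freqs[which.max(avg)] - 40), step)

  zero <- lfp_recording(numeric(2000), 1000)
  expect_true(all(wavelet_spectrogram(zero, fmin = 20, fmax = 80)$power == 0))

  # the gamma request must cover the full 30-70 Hz band
  spg <- wavelet_spectrogram(rec, fmin = analysis_band("gamma")[1],
                             fmax = analysis_band("gamma")[2])
  expect_lte(min(spg$freqs), 30)
  expect_gte(max(spg$freqs), 70)

  expect_error(wavelet_spectrogram(rec, fmin = 20, fmax = 600), "Nyquist")
})

test_that("Welch PSD conserves variance and localizes tones in noise", {
  zero <- lfp_recording(numeric(10000), 1000)
  expect_true(all(compute_psd(zero)$psd == 0))

  set.seed(7)
  wn <- lfp_recording(stats::rnorm(600 * 500), 500)
  p <- compute_psd(wn)
  df <- p$freqs[2] - p$freqs[1]
  expect_lt(abs(sum(p$psd) * df - stats::var(wn$data[, 1])) /
              stats::var(wn$data[, 1]), 0.05)

  set.seed(8)
  t <- seq.int(0, 60 * 1000 - 1) / 1000
  tone <- lfp_recording(3 * sin(2 * pi * 40 * t) + stats::rnorm(length(t)), 1000)
  pt <- compute_psd(tone)
  expect_equal(pt$freqs[which.max(pt$psd)], 40, tolerance = 1e-9)

  expect_error(compute_psd(lfp_recording(numeric(1000), 1000)), "too short")
  expect_error(compute_psd(wn, segment = c(100, 700)), "segment")
})

test_that("spectral peak descriptors match closed-form oracles", {
  # single nonzero bin
  freqs <- seq(0, 100, by = 0.5)
  psd <- numeric(length(freqs))
  psd[freqs == 40] <- 5
  s1 <- summarize_spectrum(list(freqs = freqs, psd = psd), c(30, 70))
  expect_equal(s1$f, 40)
  expect_equal(s1$Power, 5)
  expect_lte(s1$FWHM, 0.5)

  # Lorentzian centered 42 Hz, half-width 3 Hz on a fine grid:
  # FWHM = 2*gamma, AuC = A*gamma*pi/2 between the half-max crossings
  fg <- seq(0, 100, by = 0.01)
  A <- 10
  gam <- 3
  lor <- A * gam^2 / (gam^2 + (fg - 42)^2)
  s2 <- summarize_spectrum(list(freqs = fg, psd = lor), c(30, 70))
  expect_equal(s2$f, 42, tolerance = 1e-6)
  expect_lt(abs(s2$FWHM - 2 * gam) / (2 * gam), 0.02)
  expect_lt(abs(s2$AuC - A * gam * pi / 2) / (A * gam * pi / 2), 0.05)

  # band restriction: a larger 10 Hz peak outside gamma must not win
  two <- 8 * exp(-(fg - 10)^2 / 2) + 4 * exp(-(fg - 45)^2 / 2)
  s3 <- summarize_spectrum(list(freqs = fg, psd = two), "gamma")
  expect_equal(s3$f, 45, tolerance = 0.02)

  # monotone-in-band spectrum (max on the edge) is flagged
  s4 <- summarize_spectrum(list(freqs = fg, psd = fg), c(30, 70))
  expect_true(s4$flagged)
  expect_error(summarize_spectrum(list(freqs = fg, psd = lor), c(30, 200)),
               "within")
})

test_that("TAU recovers the AR(2) analytic decay, flags undamped rhythms, and is amplitude invariant", {
  r <- 0.999
  fs <- 5000
  rec <- ar2_recording(r, 40, fs = fs, duration = 120, seed = 2)
  ac <- autocorr_tau(rec, band = NULL, max_lag = 0.5)
  expect_false(ac$non_decaying)
  expect_lt(abs(ac$TAU - (-1 / fs / log(r))) / (-1 / fs / log(r)), 0.1)
  expect_true(all(ac$peak_values <= 1 & ac$peak_values >= -1))

  # pure sinusoid: autocorrelation peaks do not decay
  expect_true(autocorr_tau(sine_recording(40, 1000, 20), band = NULL,
                           max_lag = 0.5)$non_decaying)

  # TAU is invariant under amplitude scaling (normalized autocorrelation)
  rec10 <- lfp_recording(10 * rec$data[, 1], fs)
  ac10 <- autocorr_tau(rec10, band = NULL, max_lag = 0.5)
  expect_lt(abs(ac10$TAU - ac$TAU) / ac$TAU, 0.01)

  expect_error(autocorr_tau(sine_recording(40, 1000, 20), band = NULL,
                            max_lag = 0.03), "peaks")
  expect_error(autocorr_tau(sine_recording(40, 1000, 2), max_lag = 0.5),
               "10 x")
})

test_that("spectral sharpness tracks oscillation stability (jitter ladders)", {
  fwhm <- tau <- numeric(0)
  for (j in c(0.5, 2, 6)) {
    g <- quick_gam(duration = 120, freq_jitter_sd = j, amp_mod_cv = 0, seed = 11)
    fwhm <- c(fwhm, summarize_spectrum(compute_psd(g$recording), "gamma")$FWHM)
    tau <- c(tau, autocorr_tau(g$recording, band = "gamma", max_lag = 1)$TAU)
  }
  # less frequency-stable oscillations: broader peaks, faster decorrelation
  expect_true(all(diff(fwhm) > 0))
  expect_true(all(diff(tau) < 0))
})

test_that("Power and AuC increase with oscillation amplitude", {
  amps <- c(10, 20, 40, 80, 160)
  pw <- auc <- numeric(0)
  for (a in amps) {
    g <- quick_gam(duration = 60, gamma_amp = a, seed = 21)
    s <- summarize_spectrum(compute_psd(g$recording), "gamma")
    pw <- c(pw, s$Power)
    auc <- c(auc, s$AuC)
  }
  expect_true(all(diff(pw) > 0))
  expect_true(all(diff(auc) > 0))
})

test_that("normalized power time course is flat for stationary gamma and quarters when amplitude halves", {
  g <- quick_gam(duration = 300, seed = 31)
  sp <- wavelet_spectrogram(g$recording, fmin = 30, fmax = 70)
  tc <- normalized_power_timecourse(sp, "gamma")   # default 60 s windows
  expect_equal(nrow(tc), 5)
  expect_true(all(abs(tc$power_norm - 1) < 0.15))

  # amplitude halved after 180 s -> power ratio 0.25
  fs <- 1000
  t <- seq.int(0, 360 * fs - 1) / fs
  amp <- ifelse(t < 180, 40, 20)
  rec <- lfp_recording(amp * sin(2 * pi * 40 * t), fs)
  tc2 <- normalized_power_timecourse(
    wavelet_spectrogram(rec, fmin = 30, fmax = 70), "gamma", window = 60)
  ratio <- mean(tc2$power_norm[4:6]) / mean(tc2$power_norm[1:3])
  expect_lt(abs(ratio - 0.25), 0.05)

  expect_error(normalized_power_timecourse(sp, c(200, 300)), "no spectrogram")
})
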