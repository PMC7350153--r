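test_that("burst detector recovers seeded bursts and stays silent without them", {
  # no bursts -> no detections
  g0 <- quick_gam(duration = 300, seed = 8)
  b0 <- detect_bursts(g0$recording, switch_time = 120)
  expect_false(b0$has_bursts)
  expect_equal(b0$incidence, 0)

  # seeded bursts at 0.3/s after the switch
  g <- quick_gam(duration = 420, burst_rate = 0.3, burst_start = 120, seed = 7)
  b <- detect_bursts(g$recording, switch_time = 120)
  sc <- score_events(b$events$time_s, g$truth$events$time_s)
  expect_gte(sc$f1, 0.95)
  truth_inc <- nrow(g$truth$events) / 300
  expect_lt(abs(b$incidence - truth_inc) / truth_inc, 0.1)
  expect_true(all(b$events$time_s >= 120))
  expect_equal(length(b$intervals), nrow(b$events) - 1L)

  expect_error(detect_bursts(g$recording, switch_time = 30), "60 s")
  expect_error(detect_bursts(g$recording, switch_time = 1000), "within")
})

test_that("burst onset is reported in minutes after the condition switch", {
  # single injected burst 120 s after the switch -> onset = 2.0 min
  fs <- 1000
  t <- seq.int(0, 400 * fs - 1) / fs
  set.seed(6)
  x <- 30 * sin(2 * pi * 40 * t) + stats::rnorm(length(t), sd = 2)
  i <- which(t >= 240 & t < 240.04)
  x[i] <- x[i] + 600 * sin(pi * seq_along(i) / length(i))^2
  b <- detect_bursts(lfp_recording(x, fs), switch_time = 120)
  expect_true(b$has_bursts)
  expect_equal(nrow(b$events), 1L)
  expect_equal(b$onset_min, 2.0, tolerance = 0.01)
})

test_that("SPW-R detector matches ground truth and ripples are counted only above 180 Hz", {
  g <- gen_recording(synth_spec("spwr", duration = 300, sampling_rate = 2500,
                                seed = 5))
  sp <- detect_spwr(g$recording)
  sc <- score_events(sp$events$time_s, g$truth$events$time_s)
  expect_gte(sc$f1, 0.95)
  truth_inc <- nrow(g$truth$events) / 5
  expect_lt(abs(sp$incidence - truth_inc) / truth_inc, 0.1)
  expect_lte(abs(stats::median(sp$events$ripples) - 5), 1)
  expect_true(all(sp$events$duration_ms > 0))

  # events whose fast component sits at 100 Hz carry no ripples in the
  # >180 Hz sense
  g100 <- gen_recording(synth_spec("spwr", duration = 300, sampling_rate = 2500,
                                   ripple_freq = 100, seed = 12))
  sp100 <- detect_spwr(g100$recording)
  expect_gte(nrow(sp100$events), 1L)
  expect_equal(stats::median(sp100$events$ripples), 0)

  # noise-only recording: no events at default thresholds
  ns <- gen_recording(synth_spec("spwr", duration = 300, sampling_rate = 2500,
                                 spwr_rate = 0, seed = 6))
  expect_equal(detect_spwr(ns$recording)$incidence, 0)

  expect_error(detect_spwr(gen_recording(synth_spec("gam", duration = 10,
                                                    sampling_rate = 500))$recording),
               "ripple band")
})

test_that("detection quality degrades monotonically as events shrink toward the noise", {
  f1 <- vapply(c(150, 45, 22), function(a) {
    g <- gen_recording(synth_spec("spwr", duration = 300, sampling_rate = 2500,
                                  spw_amp = a, seed = 13))
    score_events(detect_spwr(g$recording)$events$time_s,
                 g$truth$events$time_s)$f1
  }, numeric(1))
  expect_true(all(diff(f1) < 0))
  expect_gte(f1[1], 0.95)
})

test_that("group summaries follow the median/IQR reporting convention", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$p25, 2)
  expect_equal(s$p75, 4)
  expect_equal(s$iqr, 2)
  expect_equal(c(s$min, s$max), c(1, 5))

  s1 <- summarize_group(7)
  expect_equal(s1$median, 7)
  expect_equal(s1$iqr, 0)

  set.seed(15)
  sn <- summarize_group(stats::rnorm(1000))
  expect_lt(abs(sn$median), 0.1)
  expect_lt(abs(sn$iqr - 1.349), 0.1)

  sf <- summarize_group(c(0.3, 0.2, 0), with_events = c(TRUE, TRUE, FALSE))
  expect_equal(sf$fraction_with_events, 2 / 3)
  expect_error(summarize_group(numeric(0)), "no finite")
})

test_that("event scoring handles matches, misses and false alarms", {
  sc <- score_events(c(1.00, 2.04, 5), c(1.01, 2, 3))
  expect_equal(c(sc$tp, sc$fp, sc$fn), c(2L, 1L, 1L))
  expect_equal(sc$f1, 2 * (2 / 3) * (2 / 3) / (4 / 3))
  expect_equal(score_events(numeric(0), c(1, 2))$recall, 0)
  expect_equal(score_events(c(1, 2), c(1, 2))$f1, 1)
})
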