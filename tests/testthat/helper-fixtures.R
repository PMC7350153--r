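# Shared fixture builders. Short recordings use reduced sampling rates to
# keep the default test run fast; every generated fixture is seeded.

# a pure sinusoid recording
sine_recording <- function(freq, fs = 5000, duration = 10, amp = 1) {
  t <- seq.int(0L, round(duration * fs) - 1L) / fs
  lfp_recording(amp * sin(2 * pi * freq * t), fs)
}

# AR(2) process with complex poles at f0 Hz, pole radius r
ar2_recording <- function(r, f0, fs = 5000, duration = 120, seed = 1) {
  set.seed(seed)
  x <- stats::filter(stats::rnorm(round(duration * fs)),
                     c(2 * r * cos(2 * pi * f0 / fs), -r^2),
                     method = "recursive")
  lfp_recording(as.numeric(x), fs)
}

# small gamma recording at an economical sampling rate
quick_gam <- function(duration = 60, fs = 1000, ..., seed = 1) {
  gen_recording(synth_spec("gam", duration = duration, sampling_rate = fs,
                           ..., seed = seed))
}
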