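#' Synthetic recording specification
#'
#' Describes one synthetic LFP recording emulating a hippocampal slice
#' network state: persistent gamma (`"gam"`), theta-nested gamma
#' (`"thegam"`) or sharp wave-ripples (`"spwr"`). All amplitudes are in
#' microvolts; the generator is fully deterministic given `seed`.
#'
#' The stationary gamma state is a sinusoid at `gamma_freq` whose amplitude
#' fluctuates slowly (coefficient of variation `amp_mod_cv`) and whose
#' instantaneous frequency carries mean-reverting jitter of standard
#' deviation `freq_jitter_sd` (Hz), on top of 1/f background noise. The
#' theta-gamma state multiplies the gamma envelope by a theta-phase
#' modulation waveform of depth `theta_mod_depth`, emulating sinusoidal
#' optogenetic drive. The sharp wave-ripple state superimposes Poisson
#' events (rate `spwr_rate` per minute) on the background, each a
#' Gaussian-windowed monophasic sharp wave of full width at half maximum
#' `spw_width` ms carrying `ripple_cycles` ripple cycles at `ripple_freq`.
#' If `burst_rate > 0`, stereotyped biphasic bursts (5 ms rise, 30 ms decay)
#' are added after `burst_start`, modelling moderate hyperexcitability.
#'
#' @param state one of `"gam"`, `"thegam"`, `"spwr"`.
#' @param duration recording length in seconds.
#' @param sampling_rate Hz; must be at least 4 x the fastest oscillation.
#' @param gamma_freq,gamma_amp gamma oscillation frequency (Hz) and peak
#'   amplitude (µV); the paper's cholinergically induced gamma sits around
#'   40 Hz within the 30-70 Hz band.
#' @param amp_mod_cv coefficient of variation of the slow gamma amplitude
#'   modulation (dimensionless).
#' @param freq_jitter_sd standard deviation of the Ornstein-Uhlenbeck
#'   instantaneous-frequency jitter (Hz); larger values broaden the spectral
#'   peak and shorten the autocorrelation decay.
#' @param theta_freq,theta_mod_depth theta drive frequency (Hz) and
#'   modulation depth in `[0, 1]` (theta-gamma state only).
#' @param spwr_rate sharp wave-ripple event rate, events per minute.
#' @param ripple_freq,ripple_cycles ripple oscillation frequency (Hz; ripples
#'   are defined as >180 Hz) and number of cycles per event.
#' @param spw_amp,spw_width sharp wave peak amplitude (µV) and full width at
#'   half maximum (ms).
#' @param burst_rate,burst_amp,burst_start burst rate (events/s), amplitude
#'   (µV) and onset time of the condition switch (s).
#' @param noise_exponent,noise_amp 1/f background: spectral exponent and
#'   standard deviation (µV).
#' @param n_channels 1 (CA3 only) or 2 (CA3 and CA1).
#' @param channel_lag CA3 -> CA1 propagation delay in ms (2-channel only).
#' @param channel_noise_corr fraction in `[0, 1]` of channel-2 noise shared
#'   with channel 1.
#' @param seed integer RNG seed.
#' @return A validated list of class `synth_spec`.
#' @export
synth_spec <- function(state = c("gam", "thegam", "spwr"),
                       duration = 600, sampling_rate = 5000,
                       gamma_freq = 40, gamma_amp = 50,
                       amp_mod_cv = 0.25, freq_jitter_sd = 1,
                       theta_freq = 5, theta_mod_depth = 1,
                       spwr_rate = 12, ripple_freq = 200, ripple_cycles = 5,
                       spw_amp = 150, spw_width = 50,
                       burst_rate = 0, burst_amp = 400, burst_start = 0,
                       noise_exponent = 1, noise_amp = 10,
                       n_channels = 1, channel_lag = 5, channel_noise_corr = 0,
                       seed = 1L) {
  state <- match.arg(state)
  spec <- list(state = state, duration = duration, sampling_rate = sampling_rate,
               gamma_freq = gamma_freq, gamma_amp = gamma_amp,
               amp_mod_cv = amp_mod_cv, freq_jitter_sd = freq_jitter_sd,
               theta_freq = theta_freq, theta_mod_depth = theta_mod_depth,
               spwr_rate = spwr_rate, ripple_freq = ripple_freq,
               ripple_cycles = ripple_cycles, spw_amp = spw_amp,
               spw_width = spw_width, burst_rate = burst_rate,
               burst_amp = burst_amp, burst_start = burst_start,
               noise_exponent = noise_exponent, noise_amp = noise_amp,
               n_channels = as.integer(n_channels), channel_lag = channel_lag,
               channel_noise_corr = channel_noise_corr, seed = as.integer(seed))
  validate_synth_spec(spec)
  structure(spec, class = "synth_spec")
}

validate_synth_spec <- function(s) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(s$duration) || s$duration <= 0) stop("`duration` must be > 0")
  if (!num1(s$sampling_rate) || s$sampling_rate <= 0) stop("`sampling_rate` must be > 0")
  for (f in c("gamma_amp", "spw_amp", "burst_amp", "noise_amp", "amp_mod_cv",
              "freq_jitter_sd", "spwr_rate", "burst_rate"))
    if (!num1(s[[f]]) || s[[f]] < 0) stop("`", f, "` must be >= 0")
  if (s$theta_mod_depth < 0 || s$theta_mod_depth > 1)
    stop("`theta_mod_depth` must lie in [0, 1]")
  if (s$channel_noise_corr < 0 || s$channel_noise_corr > 1)
    stop("`channel_noise_corr` must lie in [0, 1]")
  fmax <- if (s$state == "spwr") max(s$gamma_freq, s$ripple_freq) else s$gamma_freq
  if (s$sampling_rate < 4 * fmax)
    stop(sprintf("`sampling_rate` (%g Hz) must be >= 4 x the fastest oscillation (%g Hz)",
                 s$sampling_rate, fmax))
  if (!s$n_channels %in% 1:2) stop("`n_channels` must be 1 or 2")
  invisible(s)
}

# run code with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Poisson event times on (t0, t1) thinned to a minimum separation, so the
# ground truth stays unambiguous for event-matching scores
poisson_times <- function(rate_per_s, t0, t1, min_sep) {
  if (rate_per_s <= 0 || t1 <= t0) return(numeric(0))
  n_draw <- max(20L, ceiling(1.5 * rate_per_s * (t1 - t0)) + 10L)
  t <- t0 + cumsum(stats::rexp(n_draw, rate_per_s))
  while (length(t) && t[length(t)] < t1) {
    t <- c(t, t[length(t)] + cumsum(stats::rexp(n_draw, rate_per_s)))
  }
  t <- t[t < t1]
  if (!length(t)) return(numeric(0))
  keep <- rep(FALSE, length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (t[i] - last >= min_sep) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  t[keep]
}

# mean-reverting (OU) process on the sample grid, stationary sd = sd, tau in s
ou_process <- function(n, fs, sd, tau = 1) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-1 / (fs * tau))
  e <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  e[1L] <- stats::rnorm(1L, sd = sd)   # stationary start
  as.numeric(stats::filter(e, a, method = "recursive"))
}

# difference-of-exponentials transient, peak-normalized
dexp_pulse <- function(t, rise, decay) {
  w <- ifelse(t < 0, 0, exp(-t / decay) - exp(-t / rise))
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  w / (exp(-tp / decay) - exp(-tp / rise))
}

#' Generate a synthetic LFP recording with ground truth
#'
#' Produces a seeded [lfp_recording()] for the network state described by a
#' [synth_spec()], together with the ground-truth event annotations needed to
#' score detectors. Identical specs (including the seed) yield bit-identical
#' output.
#'
#' @param spec a [synth_spec()].
#' @return A list of class `synth_recording` with elements `recording` (an
#'   [lfp_recording()]) and `truth` (class `ground_truth`: a `data.frame`
#'   `events` with columns `time_s`, `amp_uV`, `kind`, `ripple_count`, plus
#'   the generating spec).
#' @examples
#' g <- gen_recording(synth_spec("gam", duration = 10, seed = 1))
#' g$recording
#' @export
gen_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  validate_synth_spec(spec)
  with_seed(spec$seed, {
    fs <- spec$sampling_rate
    n <- round(spec$duration * fs)
    t <- (seq_len(n) - 1L) / fs
    sig <- numeric(n)
    events <- data.frame(time_s = numeric(0), amp_uV = numeric(0),
                         kind = character(0), ripple_count = integer(0))

    if (spec$state %in% c("gam", "thegam")) {
      # instantaneous frequency with OU jitter -> phase by integration
      fi <- spec$gamma_freq + ou_process(n, fs, spec$freq_jitter_sd, tau = 1)
      phase <- 2 * pi * cumsum(fi) / fs
      env <- pmax(0, 1 + ou_process(n, fs, spec$amp_mod_cv, tau = 0.5))
      if (spec$state == "thegam") {
        th_phase <- 2 * pi * spec$theta_freq * t
        mod <- (1 - spec$theta_mod_depth) +
          spec$theta_mod_depth * (1 + cos(th_phase)) / 2
        env <- env * mod
        sig <- sig + 0.5 * spec$gamma_amp * cos(th_phase)
      }
      sig <- sig + spec$gamma_amp * env * sin(phase)
    }

    if (spec$state == "spwr" && spec$spwr_rate > 0) {
      w_s <- spec$spw_width / 1000
      times <- poisson_times(spec$spwr_rate / 60, 0, spec$duration, 2 * w_s)
      if (length(times)) {
        amps <- spec$spw_amp * pmax(0.2, 1 + 0.1 * stats::rnorm(length(times)))
        sigma <- w_s / (2 * sqrt(2 * log(2)))
        half_r <- spec$ripple_cycles / spec$ripple_freq / 2
        for (k in seq_along(times)) {
          i0 <- max(1L, floor((times[k] - 4 * sigma) * fs) + 1L)
          i1 <- min(n, ceiling((times[k] + 4 * sigma) * fs) + 1L)
          tt <- t[i0:i1] - times[k]
          sig[i0:i1] <- sig[i0:i1] - amps[k] * exp(-tt^2 / (2 * sigma^2))
          rip <- abs(tt) <= half_r
          sig[i0:i1][rip] <- sig[i0:i1][rip] +
            0.4 * amps[k] * cos(pi * tt[rip] / (2 * half_r))^2 *
            cos(2 * pi * spec$ripple_freq * tt[rip])
        }
        events <- rbind(events, data.frame(
          time_s = times, amp_uV = amps, kind = "spwr",
          ripple_count = rep(as.integer(spec$ripple_cycles), length(times))))
      }
    }

    if (spec$burst_rate > 0) {
      times <- poisson_times(spec$burst_rate, spec$burst_start, spec$duration, 0.5)
      if (length(times)) {
        amps <- spec$burst_amp * pmax(0.2, 1 + 0.1 * stats::rnorm(length(times)))
        span <- 0.25  # s of waveform support
        for (k in seq_along(times)) {
          i0 <- max(1L, floor(times[k] * fs) + 1L)
          i1 <- min(n, ceiling((times[k] + span) * fs))
          tt <- t[i0:i1] - times[k]
          w <- dexp_pulse(tt, 0.005, 0.030) - 0.4 * dexp_pulse(tt - 0.030, 0.010, 0.060)
          sig[i0:i1] <- sig[i0:i1] + amps[k] * w
        }
        events <- rbind(events, data.frame(
          time_s = times, amp_uV = amps, kind = "burst",
          ripple_count = rep(NA_integer_, length(times))))
      }
    }

    noise1 <- if (spec$noise_amp > 0)
      spec$noise_amp * colored_noise(n, fs, spec$noise_exponent) else numeric(n)
    ch1 <- sig + noise1

    if (spec$n_channels == 2L) {
      lag_n <- round(spec$channel_lag / 1000 * fs)
      delay <- function(x) if (lag_n == 0L) x else c(rep(0, lag_n), x[seq_len(n - lag_n)])
      rho <- spec$channel_noise_corr
      noise2 <- if (spec$noise_amp > 0)
        spec$noise_amp * colored_noise(n, fs, spec$noise_exponent) else numeric(n)
      ch2 <- delay(sig) + rho * delay(noise1) + sqrt(1 - rho^2) * noise2
      rec <- lfp_recording(cbind(ch1, ch2), fs, c("ca3_uV", "ca1_uV"))
    } else {
      rec <- lfp_recording(ch1, fs, "ca3_uV")
    }

    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL
    truth <- structure(list(events = events, spec = spec), class = "ground_truth")
    structure(list(recording = rec, truth = truth), class = "synth_recording")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d event(s) [%s], state %s\n",
              nrow(x$events), paste(unique(x$events$kind), collapse = ", "),
              x$spec$state))
  invisible(x)
}

#' @export
print.synth_recording <- function(x, ...) {
  print(x$recording)
  print(x$truth)
  invisible(x)
}

#' Generate a noisy synthetic oxygen depth profile
#'
#' Evaluates the steady-state forward model [forward_profile()] on a depth
#' grid and adds i.i.d. Gaussian measurement noise, emulating a microsensor
#' depth profile through a slice.
#'
#' @param model an [oxygen_model()].
#' @param depth_grid depths in µm, inside `[0, L]`.
#' @param noise_sd Gaussian noise standard deviation (concentration units).
#' @param seed integer RNG seed.
#' @param atmosphere label for the gas phase above the slice (`"95%"` or
#'   `"20%"` oxygen), recorded as metadata.
#' @return An `oxygen_profile` (see [oxygen_profile()]).
#' @export
gen_oxygen_profile <- function(model, depth_grid, noise_sd = 0, seed = 1L,
                               atmosphere = "95%") {
  stopifnot(inherits(model, "oxygen_model"))
  depth_grid <- as.numeric(depth_grid)
  if (any(depth_grid < 0 | depth_grid > model$L))
    stop("`depth_grid` must lie within [0, L] = [0, ", model$L, "] µm")
  if (is.unsorted(depth_grid, strictly = TRUE))
    stop("`depth_grid` must be strictly increasing")
  fwd <- forward_profile(model)
  conc <- stats::spline(fwd$depth, fwd$concentration, xout = depth_grid)$y
  if (noise_sd > 0) {
    conc <- conc + with_seed(seed, stats::rnorm(length(depth_grid), sd = noise_sd))
    conc <- pmax(conc, 0)  # a microsensor cannot report negative concentration
  }
  oxygen_profile(depth_grid, conc, atmosphere = atmosphere,
                 meta = list(synthetic = TRUE, noise_sd = noise_sd, seed = seed))
}
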