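#' Analysis frequency bands
#'
#' The gamma band is fixed to 30-70 Hz and the theta band to 3-8 Hz; the
#' ripple band starts above 180 Hz.
#'
#' @param name one of `"gamma"`, `"theta"`, `"ripple"`, `"spw"`.
#' @return numeric length-2 vector `c(low, high)` in Hz.
#' @export
analysis_band <- function(name = c("gamma", "theta", "ripple", "spw")) {
  switch(match.arg(name),
         gamma = c(30, 70),
         theta = c(3, 8),
         ripple = c(180, 300),
         spw = c(2, 45))
}

#' Morlet wavelet spectrogram
#'
#' Time-frequency power of one LFP channel by continuous wavelet transform
#' with complex Morlet wavelets (default 6 cycles), computed by FFT
#' convolution on a linear frequency grid. Power is the squared magnitude of
#' the wavelet coefficients, in arbitrary units. To keep memory bounded the
#' power is block-averaged to an output time step `dt_out` (block means
#' preserve band power time courses exactly).
#'
#' @param rec an [lfp_recording()].
#' @param channel channel index or label.
#' @param fmin,fmax frequency range in Hz; `fmax` must stay below Nyquist.
#'   The convenience value `band = "gamma"` covers 30-70 Hz.
#' @param n_freqs number of linearly spaced frequencies; default gives a
#'   1 Hz step.
#' @param n_cycles Morlet width parameter (cycles).
#' @param dt_out output time resolution in seconds.
#' @return An object of class `spectrogram`: list with `times` (s), `freqs`
#'   (Hz) and `power` (freq x time matrix, a.u.).
#' @export
wavelet_spectrogram <- function(rec, channel = 1L, fmin = 30, fmax = 70,
                                n_freqs = NULL, n_cycles = 6, dt_out = 0.01) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (!(fmin < fmax)) stop("`fmin` must be < `fmax`")
  if (fmin <= 0) stop("`fmin` must be > 0")
  if (fmax >= rec$fs / 2)
    stop(sprintf("`fmax` (%g Hz) must be below Nyquist (%g Hz)", fmax, rec$fs / 2))
  if (is.null(n_freqs)) n_freqs <- max(2L, round(fmax - fmin) + 1L)
  freqs <- seq(fmin, fmax, length.out = n_freqs)

  x <- channel_vector(rec, channel)
  n <- length(x)
  fs <- rec$fs
  # pad by ~2 s: Morlet support (n_cycles / fmin) is well under that, so
  # circular wrap-around is negligible
  nf <- stats::nextn(n + 2L * round(fs), 2)
  X <- stats::fft(c(x - mean(x), rep(0, nf - n)))
  fgrid <- c(seq.int(0L, nf %/% 2L), seq.int(-(nf - nf %/% 2L - 1L), -1L)) * (fs / nf)

  block <- max(1L, round(dt_out * fs))
  n_out <- n %/% block
  if (n_out < 1L) stop("`dt_out` exceeds the recording duration")
  power <- matrix(0, nrow = n_freqs, ncol = n_out)
  for (k in seq_len(n_freqs)) {
    f0 <- freqs[k]
    sigma_f <- f0 / n_cycles
    # analytic Morlet: Gaussian on the positive-frequency axis, peak 1
    H <- ifelse(fgrid > 0, exp(-(fgrid - f0)^2 / (2 * sigma_f^2)), 0)
    w <- stats::fft(X * H, inverse = TRUE) / nf
    p <- Mod(w[seq_len(n_out * block)])^2
    power[k, ] <- colMeans(matrix(p, nrow = block))
  }
  times <- (seq_len(n_out) - 0.5) * block / fs
  structure(list(times = times, freqs = freqs, power = power),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d frequencies [%g-%g Hz] x %d time bins [%g-%g s]\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @param x a `spectrogram`.
#' @param ... passed to [graphics::image()].
#' @rdname wavelet_spectrogram
#' @export
plot.spectrogram <- function(x, ...) {
  graphics::image(x$times, x$freqs, t(x$power),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "time (s)", ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Welch power spectral density
#'
#' One-sided PSD of one channel by Welch's method: Hann-windowed segments
#' (default 2 s, 50% overlap), giving about 0.5 Hz resolution — enough to
#' resolve the width of a 40 Hz gamma peak. Units are µV²/Hz, treated as
#' arbitrary units downstream.
#'
#' @param rec an [lfp_recording()].
#' @param channel channel index or label.
#' @param segment optional `c(t0, t1)` analysis window in seconds (e.g. the
#'   last 5 minutes of a condition); default is the whole recording.
#' @param window_s Welch segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return An object of class `psd`: list with `freqs` (Hz), `psd`
#'   (power density) and `n_segments`.
#' @export
compute_psd <- function(rec, channel = 1L, segment = NULL, window_s = 2,
                        overlap = 0.5) {
  stopifnot(inherits(rec, "lfp_recording"))
  x <- channel_vector(rec, channel)
  fs <- rec$fs
  if (!is.null(segment)) {
    if (length(segment) != 2L || segment[1] < 0 || segment[2] > rec$duration ||
        segment[1] >= segment[2])
      stop("`segment` must be c(t0, t1) within the recording")
    x <- x[(floor(segment[1] * fs) + 1L):min(length(x), ceiling(segment[2] * fs))]
  }
  nwin <- round(window_s * fs)
  if (length(x) < 2L * nwin)
    stop(sprintf("segment too short for Welch PSD: need >= %g s (2 windows), got %.3g s",
                 2 * window_s, length(x) / fs))
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq.int(1L, length(x) - nwin + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, nwin - 1L) / nwin)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nh <- nwin %/% 2L
  acc <- numeric(nh + 1L)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[seq_len(nh + 1L)])^2 * scale
    acc <- acc + P
  }
  psd <- acc / length(starts)
  psd[2:nh] <- 2 * psd[2:nh]   # one-sided: double all but DC and Nyquist
  structure(list(freqs = seq.int(0L, nh) * fs / nwin, psd = psd,
                 n_segments = length(starts)),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins, 0-%g Hz (Δf = %.4g Hz), %d segments\n",
              length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1],
              x$n_segments))
  invisible(x)
}

#' @param x a `psd`.
#' @param ... passed to [graphics::plot()].
#' @rdname compute_psd
#' @export
plot.psd <- function(x, ...) {
  graphics::plot(x$freqs, x$psd, type = "l", xlab = "frequency (Hz)",
                 ylab = "PSD (a.u.)", ...)
  invisible(x)
}

#' Scalar descriptors of a spectral peak
#'
#' Extracts the standard oscillation metrics from a power spectrum within an
#' analysis band: peak frequency `f` (argmax of the PSD in the band), peak
#' power `Power` (the PSD there), `FWHM` (distance between the two half-
#' maximum crossings located by linear interpolation around the peak) and
#' `AuC` (trapezoidal integral of the PSD between those crossings, so that
#' AuC and FWHM describe the same spectral region). Ties at equal maxima are
#' broken toward the lowest frequency. If the maximum sits on a band edge
#' with no local maximum strictly inside the band the result is flagged.
#'
#' @param spectrum a `psd` object or a list with `freqs` and `psd`.
#' @param band `c(low, high)` Hz or a band name understood by
#'   [analysis_band()]; default `"gamma"` (30-70 Hz).
#' @return An object of class `spectrum_summary`: list with `f`, `Power`,
#'   `FWHM`, `AuC`, the half-maximum crossing frequencies `hm_lo`/`hm_hi`,
#'   `band` and `flagged`.
#' @export
summarize_spectrum <- function(spectrum, band = "gamma") {
  if (is.character(band)) band <- analysis_band(band)
  freqs <- spectrum$freqs
  psd <- spectrum$psd
  if (band[1] < min(freqs) || band[2] > max(freqs))
    stop("`band` must lie within the spectrum's frequency range")
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) < 2L) stop("band contains fewer than 2 frequency bins")
  i_pk <- sel[which.max(psd[sel])]          # which.max: first (lowest-f) tie wins
  f <- freqs[i_pk]
  Power <- psd[i_pk]
  flagged <- FALSE
  if (i_pk == sel[1L] || i_pk == sel[length(sel)]) {
    interior <- sel[-c(1L, length(sel))]
    has_local <- length(interior) > 0 &&
      any(psd[interior] > psd[interior - 1L] & psd[interior] >= psd[interior + 1L])
    if (!has_local) flagged <- TRUE
  }

  half <- Power / 2
  # walk outward from the peak to the half-maximum crossings (full spectrum,
  # not just the band, so wide peaks are measured completely)
  lo <- freqs[1L]
  found_lo <- FALSE
  for (i in seq.int(i_pk, 2L)) {
    if (psd[i - 1L] < half && psd[i] >= half) {
      lo <- freqs[i - 1L] + (freqs[i] - freqs[i - 1L]) *
        (half - psd[i - 1L]) / (psd[i] - psd[i - 1L])
      found_lo <- TRUE
      break
    }
  }
  hi <- freqs[length(freqs)]
  found_hi <- FALSE
  if (i_pk < length(freqs)) {
    for (i in seq.int(i_pk, length(freqs) - 1L)) {
      if (psd[i] >= half && psd[i + 1L] < half) {
        hi <- freqs[i] + (freqs[i + 1L] - freqs[i]) *
          (half - psd[i]) / (psd[i] - psd[i + 1L])
        found_hi <- TRUE
        break
      }
    }
  }
  if (!found_lo || !found_hi) flagged <- TRUE

  # trapezoidal integral of the PSD between the two crossings
  inner <- which(freqs > lo & freqs < hi)
  xs <- c(lo, freqs[inner], hi)
  fx <- function(f0) stats::approx(freqs, psd, xout = f0)$y
  ys <- c(fx(lo), psd[inner], fx(hi))
  auc <- if (length(xs) >= 2L) sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2) else 0

  structure(list(f = f, Power = Power, FWHM = max(hi - lo, 0), AuC = auc,
                 hm_lo = lo, hm_hi = hi, band = band, flagged = flagged),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Spectral peak in %g-%g Hz: f = %.4g Hz, Power = %.4g a.u., FWHM = %.4g Hz, AuC = %.4g%s\n",
              x$band[1], x$band[2], x$f, x$Power, x$FWHM, x$AuC,
              if (x$flagged) "  [flagged: no interior maximum]" else ""))
  invisible(x)
}

#' Autocorrelation decay time constant (TAU)
#'
#' Band-pass filters one channel, computes the normalized autocorrelation,
#' locates its positive-lag local maxima and fits a decaying exponential
#' `A * exp(-lag / TAU)` to the peak values by unweighted least squares on
#' the log peaks (non-positive peaks are excluded, and the fit uses only the
#' leading decade of the decay, peaks above 10% of `r(0)`, where the sample
#' autocorrelation is well above its estimation noise). TAU measures the
#' temporal coherence of an oscillation: rhythms with stable frequency decay
#' slowly (long TAU), jittery rhythms decay fast. If the fitted TAU exceeds
#' `max_lag` (e.g. for an undamped sinusoid) the `non_decaying` flag is set.
#'
#' @param rec an [lfp_recording()].
#' @param channel channel index or label.
#' @param band `c(low, high)` Hz, a band name, or `NULL` to skip filtering.
#' @param max_lag maximum autocorrelation lag in seconds; the recording must
#'   be at least 10 x longer.
#' @return An object of class `autocorr_summary`: `TAU` (s), `A`,
#'   `peak_lags` (s), `peak_values`, `fit_quality` (R² of the log-linear
#'   fit), `non_decaying`.
#' @export
autocorr_tau <- function(rec, channel = 1L, band = "gamma", max_lag = 0.5) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (rec$duration < 10 * max_lag)
    stop("recording must be at least 10 x `max_lag` long")
  x <- channel_vector(rec, channel)
  if (!is.null(band)) {
    if (is.character(band)) band <- analysis_band(band)
    x <- zp_filter(x, rec$fs, low = band[1], high = band[2])
  }
  ml <- round(max_lag * rec$fs)
  r <- fft_autocorr(x, ml)
  lags <- seq.int(0L, ml) / rec$fs
  # positive-lag local maxima of the autocorrelation
  i <- 2:(length(r) - 1L)
  pk <- i[r[i] > r[i - 1L] & r[i] >= r[i + 1L]]
  if (length(pk) < 3L)
    stop("fewer than 3 autocorrelation peaks in [0, max_lag]; increase `max_lag`")
  pv <- r[pk]
  pl <- lags[pk]
  # fit only the leading decade (peaks >= 10% of r(0)): below that the
  # sample-autocorrelation noise dominates and, through the concavity of the
  # log, systematically biases the unweighted log-linear fit
  cut <- which(pv <= 0.1)
  if (length(cut)) {
    n_keep <- max(cut[1L] - 1L, 3L)
    pv <- pv[seq_len(min(length(pv), n_keep))]
    pl <- pl[seq_len(length(pv))]
  }
  pos <- pv > 0           # positivity clamp: log fit needs positive peaks
  if (sum(pos) < 3L) stop("fewer than 3 positive autocorrelation peaks")
  fit <- stats::lm.fit(cbind(1, pl[pos]), log(pv[pos]))
  slope <- fit$coefficients[2L]
  r2 <- 1 - sum(fit$residuals^2) /
    max(sum((log(pv[pos]) - mean(log(pv[pos])))^2), .Machine$double.eps)
  tau <- if (slope < 0) -1 / slope else Inf
  structure(list(TAU = tau, A = exp(fit$coefficients[1L]),
                 peak_lags = pl, peak_values = pv, fit_quality = r2,
                 non_decaying = !(tau < max_lag)),
            class = "autocorr_summary")
}

#' @export
print.autocorr_summary <- function(x, ...) {
  if (x$non_decaying) {
    cat(sprintf("Autocorrelation: non-decaying (%d peaks; fitted TAU %s)\n",
                length(x$peak_lags),
                if (is.finite(x$TAU)) sprintf("%.3g s > max lag", x$TAU) else "infinite"))
  } else {
    cat(sprintf("Autocorrelation: TAU = %.4g s (A = %.3g, R² = %.3f, %d peaks)\n",
                x$TAU, x$A, x$fit_quality, length(x$peak_lags)))
  }
  invisible(x)
}

#' Normalized band-power time course
#'
#' Band-averaged wavelet power in consecutive non-overlapping windows
#' (default 1 min segments), normalized to the first window. This is the
#' form in which slow drifts of oscillation power across a condition are
#' tracked.
#'
#' @param spgram a `spectrogram` from [wavelet_spectrogram()].
#' @param band `c(low, high)` Hz or a band name.
#' @param window window length in seconds (default 60).
#' @return A `data.frame` with `t` (window centers, s) and `power_norm`.
#' @export
normalized_power_timecourse <- function(spgram, band = "gamma", window = 60) {
  stopifnot(inherits(spgram, "spectrogram"))
  if (is.character(band)) band <- analysis_band(band)
  rows <- which(spgram$freqs >= band[1] & spgram$freqs <= band[2])
  if (!length(rows)) stop("`band` selects no spectrogram frequencies")
  dt <- diff(spgram$times[1:2])
  per <- max(1L, round(window / dt))
  n_win <- length(spgram$times) %/% per
  if (n_win < 1L) stop("`window` exceeds the spectrogram duration")
  bp <- colMeans(spgram$power[rows, , drop = FALSE])
  wp <- vapply(seq_len(n_win), function(k)
    mean(bp[((k - 1L) * per + 1L):(k * per)]), numeric(1))
  data.frame(t = (seq_len(n_win) - 0.5) * per * dt,
             power_norm = wp / wp[1L])
}
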