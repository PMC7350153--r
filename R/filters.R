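# Internal signal-processing primitives.
#
# Filtering is done in the frequency domain by applying the *squared*
# magnitude response of an order-4 Butterworth design, which is exactly the
# magnitude response of forward-backward (zero-phase) time-domain filtering
# and introduces no phase shift by construction. Edges are mirror-padded to
# suppress wrap-around transients.

# squared Butterworth magnitude response |H|^2 on frequency vector f (Hz)
butter_mag2 <- function(f, low = NULL, high = NULL, order = 4L) {
  h <- rep(1, length(f))
  af <- abs(f)
  if (!is.null(high)) h <- h / (1 + (af / high)^(2L * order))
  if (!is.null(low)) {
    hp <- ifelse(af == 0, 0, 1 / (1 + (low / pmax(af, .Machine$double.xmin))^(2L * order)))
    h <- h * hp
  }
  h
}

# zero-phase band/low/high-pass of a numeric vector sampled at fs
zp_filter <- function(x, fs, low = NULL, high = NULL, order = 4L) {
  n <- length(x)
  if (n < 4L) return(x * butter_mag2(0, low, high, order))
  pad <- min(n - 1L, max(64L, ceiling(fs)))   # ~1 s mirror padding
  xp <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp)
  nf <- stats::nextn(m, 2)
  xp <- c(xp, rep(0, nf - m))
  f <- c(seq.int(0L, nf %/% 2L), seq.int(-(nf - nf %/% 2L - 1L), -1L)) * (fs / nf)
  h <- butter_mag2(f, low, high, order)
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / nf
  y[(pad + 1L):(pad + n)]
}

# amplitude envelope via the analytic signal (FFT Hilbert transform)
hilbert_envelope <- function(x) {
  n <- length(x)
  nf <- stats::nextn(n, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  h <- numeric(nf)
  h[1L] <- 1
  if (nf %% 2L == 0L) {
    h[nf %/% 2L + 1L] <- 1
    h[2L:(nf %/% 2L)] <- 2
  } else {
    h[2L:((nf + 1L) %/% 2L)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / nf
  Mod(a[seq_len(n)])
}

# biased normalized autocorrelation r[0..max_lag_samples] via FFT
fft_autocorr <- function(x, max_lag_samples) {
  x <- x - mean(x)
  n <- length(x)
  nf <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, rep(0, nf - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nf
  ac <- ac[seq_len(max_lag_samples + 1L)]
  ac / ac[1L]
}

# Gaussian 1/f^alpha noise, unit variance, deterministic under the caller's RNG
colored_noise <- function(n, fs, exponent = 1) {
  nf <- stats::nextn(n, 2)
  w <- stats::rnorm(nf)
  W <- stats::fft(w)
  f <- c(seq.int(0L, nf %/% 2L), seq.int(-(nf - nf %/% 2L - 1L), -1L)) * (fs / nf)
  shape <- c(0, abs(f[-1L])^(-exponent / 2))
  y <- Re(stats::fft(W * shape, inverse = TRUE)) / nf
  y <- y[seq_len(n)]
  s <- stats::sd(y)
  if (s > 0) y / s else y
}
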