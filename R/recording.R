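#' Local field potential recording
#'
#' Container for a uniformly sampled, one- or two-channel extracellular LFP
#' trace. Samples are stored as a numeric matrix (rows = time, columns =
#' channels, microvolts) together with the sampling rate.
#'
#' @param data numeric vector or matrix of samples in microvolts; one column
#'   per channel.
#' @param fs sampling rate in Hz.
#' @param channels optional character vector of channel labels. Defaults to
#'   `"ca3_uV"` for the first channel and `"ca1_uV"` for the second, the
#'   convention used throughout for CA3 -> CA1 recordings.
#' @return An object of class `lfp_recording` with elements `data`, `fs`,
#'   `channels`, `n` (samples) and `duration` (seconds).
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 40 * seq(0, 1, by = 1 / 5000)), fs = 5000)
#' rec
#' @export
lfp_recording <- function(data, fs, channels = NULL) {
  if (is.vector(data)) data <- matrix(as.numeric(data), ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (ncol(data) < 1L) stop("recording must contain at least one channel")
  if (is.null(channels)) {
    channels <- c("ca3_uV", "ca1_uV", paste0("ch", seq_len(ncol(data))))[seq_len(ncol(data))]
  }
  if (length(channels) != ncol(data))
    stop("`channels` must match the number of data columns")
  colnames(data) <- channels
  structure(
    list(data = data, fs = as.numeric(fs), channels = channels,
         n = nrow(data), duration = nrow(data) / fs),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("LFP recording: %d channel(s) [%s], %.6g s at %g Hz (%d samples)\n",
              ncol(x$data), paste(x$channels, collapse = ", "),
              x$duration, x$fs, x$n))
  invisible(x)
}

#' @export
as.data.frame.lfp_recording <- function(x, ...) {
  data.frame(time_s = (seq_len(x$n) - 1L) / x$fs, x$data, check.names = FALSE)
}

#' @param x an `lfp_recording`.
#' @param channel channel index or label.
#' @param t0,t1 plotted time window in seconds.
#' @param ... passed to [graphics::plot()].
#' @rdname lfp_recording
#' @export
plot.lfp_recording <- function(x, channel = 1L, t0 = 0, t1 = min(x$duration, 5), ...) {
  ch <- resolve_channel(x, channel)
  i <- seq.int(max(1L, floor(t0 * x$fs) + 1L), min(x$n, ceiling(t1 * x$fs)))
  graphics::plot((i - 1L) / x$fs, x$data[i, ch], type = "l",
                 xlab = "time (s)", ylab = paste0(x$channels[ch], " (µV)"), ...)
  invisible(x)
}

# map channel label or index to a column index
resolve_channel <- function(rec, channel) {
  if (is.character(channel)) {
    ch <- match(channel, rec$channels)
    if (is.na(ch)) stop("unknown channel label: ", channel)
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > ncol(rec$data)) stop("channel index out of range: ", channel)
  }
  ch
}

# extract one channel as a numeric vector
channel_vector <- function(rec, channel) {
  rec$data[, resolve_channel(rec, channel)]
}

#' Read and write recordings as CSV
#'
#' Recordings are exchanged as plain CSV with a `time_s` column followed by
#' one column per channel (`ca3_uV`, `ca1_uV`, ...). The time column must be
#' uniformly sampled: any step deviating from the median step by more than
#' 1 ppm (relative) is rejected, naming the first offending row.
#'
#' @param path file path.
#' @return `read_recording_csv()` returns an [lfp_recording()];
#'   `write_recording_csv()` returns `path` invisibly.
#' @export
read_recording_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L || names(dt)[1] != "time_s")
    stop("expected header `time_s` followed by at least one channel column in ", path)
  t <- as.numeric(dt[[1]])
  if (length(t) < 2L) stop("recording must contain at least 2 samples")
  steps <- diff(t)
  step <- stats::median(steps)
  if (step <= 0) stop("time column must be strictly increasing")
  bad <- which(abs(steps - step) > 1e-6 * step)
  if (length(bad))
    stop(sprintf("non-uniform sampling: step between rows %d and %d is %.9g s (expected %.9g s)",
                 bad[1] + 1L, bad[1] + 2L, steps[bad[1]], step))
  lfp_recording(as.matrix(dt[, -1, drop = FALSE]), fs = 1 / step,
                channels = names(dt)[-1])
}

#' @param rec an [lfp_recording()].
#' @rdname read_recording_csv
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  data.table::fwrite(as.data.frame(rec), path)
  invisible(path)
}
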