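# find runs of TRUE in a logical vector -> matrix of (start, end) indices
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# robust SD by iterative exclusion of suprathreshold samples (2 passes)
excluded_sd <- function(x, k, passes = 2L) {
  s <- stats::sd(x)
  for (p in seq_len(passes)) {
    keep <- abs(x - mean(x)) <= k * s
    if (!any(keep)) break
    s2 <- stats::sd(x[keep])
    if (!is.finite(s2) || s2 <= 0) break
    s <- s2
  }
  s
}

#' Detect lactate-evoked bursts
#'
#' Detects recurrent high-amplitude population bursts superimposed on
#' ongoing gamma oscillations after a condition switch. The broadband
#' envelope (rectified signal low-passed at 20 Hz) is thresholded at
#' `mean + k_sd * SD` of the pre-switch baseline envelope (baseline moments
#' computed with two passes of suprathreshold exclusion, since the threshold
#' must clear the ongoing gamma envelope). Detections closer than
#' `refractory` are merged.
#'
#' @param rec an [lfp_recording()].
#' @param channel channel index or label.
#' @param switch_time condition-switch time in seconds; at least 60 s of
#'   pre-switch baseline is required.
#' @param k_sd threshold in baseline envelope standard deviations.
#' @param refractory minimum separation between events, seconds.
#' @param env_lowpass envelope smoothing corner frequency, Hz.
#' @return An object of class `burst_set`: `events` data.frame (`time_s`,
#'   `amp_uV`), `incidence` (events/s over the post-switch period),
#'   `intervals` (s), `onset_min` (first burst, minutes after the switch),
#'   `has_bursts`, plus the threshold diagnostics.
#' @export
detect_bursts <- function(rec, channel = 1L, switch_time, k_sd = 5,
                          refractory = 0.5, env_lowpass = 20) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (switch_time < 0 || switch_time >= rec$duration)
    stop("`switch_time` must lie within the recording")
  if (switch_time < 60)
    stop("need at least 60 s of pre-switch baseline")
  x <- channel_vector(rec, channel)
  fs <- rec$fs
  env <- zp_filter(abs(x), fs, high = env_lowpass)
  i_switch <- floor(switch_time * fs) + 1L
  base <- env[seq_len(i_switch - 1L)]
  # two-pass exclusion so occasional baseline transients do not inflate SD
  m <- mean(base)
  s <- stats::sd(base)
  for (p in 1:2) {
    keep <- base <= m + k_sd * s
    if (!any(keep)) break
    m <- mean(base[keep])
    s <- stats::sd(base[keep])
  }
  thr <- m + k_sd * s
  post <- env[i_switch:length(env)]
  times <- amps <- numeric(0)
  if (is.finite(thr) && s > 0 && any(post > thr)) {
    runs <- true_runs(post > thr)
    # merge runs separated by less than the refractory period
    keep <- rep(TRUE, nrow(runs))
    if (nrow(runs) > 1L) {
      for (i in 2:nrow(runs)) {
        gap <- (runs[i, "start"] - runs[max(which(keep[1:(i - 1L)])), "end"]) / fs
        if (gap < refractory) {
          j <- max(which(keep[1:(i - 1L)]))
          runs[j, "end"] <- runs[i, "end"]
          keep[i] <- FALSE
        }
      }
    }
    runs <- runs[keep, , drop = FALSE]
    times <- amps <- numeric(nrow(runs))
    for (i in seq_len(nrow(runs))) {
      idx <- (runs[i, "start"]:runs[i, "end"]) + i_switch - 1L
      ipk <- idx[which.max(abs(x[idx]))]
      times[i] <- (ipk - 1L) / fs
      amps[i] <- max(abs(x[idx]))
    }
  }
  post_dur <- rec$duration - switch_time
  structure(list(
    events = data.frame(time_s = times, amp_uV = amps),
    incidence = length(times) / post_dur,
    intervals = if (length(times) > 1L) diff(times) else numeric(0),
    onset_min = if (length(times)) (times[1L] - switch_time) / 60 else NA_real_,
    has_bursts = length(times) > 0L,
    threshold = thr, baseline_sd = s, switch_time = switch_time
  ), class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  if (!x$has_bursts) {
    cat("Burst detection: no bursts\n")
  } else {
    cat(sprintf("Burst detection: %d bursts, incidence %.3g /s, onset %.3g min after switch\n",
                nrow(x$events), x$incidence, x$onset_min))
    cat(sprintf("  amplitude median %.4g µV; interval median %.3g s\n",
                stats::median(x$events$amp_uV),
                if (length(x$intervals)) stats::median(x$intervals) else NA))
  }
  invisible(x)
}

#' Detect sharp wave-ripple events
#'
#' Sharp wave (SPW) candidates are excursions of the SPW-band (default
#' 2-45 Hz) filtered trace beyond `k_sd` standard deviations (SD estimated
#' with two passes of event exclusion); a candidate is confirmed as an event
#' only if its peak also exceeds `k_sd_peak` SD, the usual dual-threshold
#' guard that keeps the false-positive rate on pure noise below one event
#' per minute. Event boundaries are the half-peak crossings of the filtered
#' trace; events with gaps below 20 ms are merged. Ripples are counted as
#' local maxima of the ripple-band (default 180-300 Hz, ripples being
#' defined as >180 Hz oscillations) filtered trace exceeding `ripple_k_sd`
#' times its event-free SD within the event window.
#'
#' @param rec an [lfp_recording()].
#' @param channel channel index or label.
#' @param spw_band,ripple_band analysis bands in Hz.
#' @param k_sd,k_sd_peak candidate and confirmation thresholds (SD units).
#' @param ripple_k_sd ripple-peak threshold (SD units).
#' @param merge_gap events closer than this (s) are merged.
#' @param polarity deflection polarity searched: `"auto"` (default; the sign
#'   with the larger extreme excursion — sharp waves have a stereotyped
#'   polarity within a layer, and restricting to it ignores the opposite-sign
#'   rebound lobes that zero-phase high-pass filtering adds around each
#'   event), `"neg"`, `"pos"`, or `"abs"` (both signs).
#' @return An object of class `spwr_set`: `events` data.frame (`time_s`,
#'   `amp_uV`, `duration_ms`, `ripples`), `incidence` (events/min) and
#'   threshold diagnostics.
#' @export
detect_spwr <- function(rec, channel = 1L, spw_band = analysis_band("spw"),
                        k_sd = 3, k_sd_peak = 5,
                        ripple_band = analysis_band("ripple"), ripple_k_sd = 2,
                        merge_gap = 0.02,
                        polarity = c("auto", "neg", "pos", "abs")) {
  stopifnot(inherits(rec, "lfp_recording"))
  polarity <- match.arg(polarity)
  fs <- rec$fs
  if (fs <= 2 * ripple_band[2])
    stop(sprintf("sampling rate (%g Hz) must exceed 2 x the ripple band upper edge (%g Hz)",
                 fs, ripple_band[2]))
  x <- channel_vector(rec, channel)
  xf <- zp_filter(x, fs, low = spw_band[1], high = spw_band[2])
  s <- excluded_sd(xf, k_sd)
  if (polarity == "auto")
    polarity <- if (max(xf) >= -min(xf)) "pos" else "neg"
  det <- switch(polarity, pos = xf, neg = -xf, abs = abs(xf))
  events <- data.frame(time_s = numeric(0), amp_uV = numeric(0),
                       duration_ms = numeric(0), ripples = integer(0))
  if (is.finite(s) && s > 0 && any(det > k_sd * s)) {
    runs <- true_runs(det > k_sd * s)
    peaks <- vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs[i, "start"]:runs[i, "end"]
      idx[which.max(det[idx])]
    }, integer(1))
    ok <- det[peaks] >= k_sd_peak * s        # dual-threshold confirmation
    peaks <- peaks[ok]
    if (length(peaks)) {
      # half-peak boundaries around each confirmed peak
      bounds <- t(vapply(peaks, function(ipk) {
        sgn <- sign(xf[ipk])
        half <- abs(xf[ipk]) / 2
        lo <- ipk
        while (lo > 1L && sgn * xf[lo - 1L] > half) lo <- lo - 1L
        hi <- ipk
        n <- length(xf)
        while (hi < n && sgn * xf[hi + 1L] > half) hi <- hi + 1L
        c(lo, hi)
      }, integer(2)))
      # merge events whose half-peak spans are separated by < merge_gap
      ord <- order(peaks)
      peaks <- peaks[ord]
      bounds <- bounds[ord, , drop = FALSE]
      keep <- rep(TRUE, length(peaks))
      for (i in seq_along(peaks)[-1L]) {
        j <- max(which(keep[1:(i - 1L)]))
        if ((bounds[i, 1L] - bounds[j, 2L]) / fs < merge_gap) {
          if (abs(xf[peaks[i]]) > abs(xf[peaks[j]])) {
            keep[j] <- FALSE
            bounds[i, 1L] <- min(bounds[i, 1L], bounds[j, 1L])
          } else {
            keep[i] <- FALSE
            bounds[j, 2L] <- max(bounds[i, 2L], bounds[j, 2L])
          }
        }
      }
      peaks <- peaks[keep]
      bounds <- bounds[keep, , drop = FALSE]

      # ripple counting on the event-free-calibrated ripple band
      xr <- zp_filter(x, fs, low = ripple_band[1], high = ripple_band[2])
      free <- rep(TRUE, length(xr))
      margin <- round(0.05 * fs)
      for (i in seq_along(peaks))
        free[max(1L, bounds[i, 1L] - margin):min(length(xr), bounds[i, 2L] + margin)] <- FALSE
      sr <- if (any(free)) excluded_sd(xr[free], ripple_k_sd) else stats::sd(xr)
      ripples <- vapply(seq_along(peaks), function(i) {
        idx <- bounds[i, 1L]:bounds[i, 2L]
        if (length(idx) < 3L) return(0L)
        v <- xr[idx]
        # ripple-presence gate: without a genuine fast packet (max well above
        # the event-free ripple-band noise) the count is zero, so noise peaks
        # inside the event window are not mistaken for ripples
        if (max(abs(v)) < 2 * ripple_k_sd * sr) return(0L)
        j <- 2:(length(v) - 1L)
        sum(v[j] > v[j - 1L] & v[j] >= v[j + 1L] & v[j] > ripple_k_sd * sr)
      }, integer(1))

      events <- data.frame(
        time_s = (peaks - 1L) / fs,
        amp_uV = abs(xf[peaks]),
        duration_ms = (bounds[, 2L] - bounds[, 1L] + 1L) / fs * 1000,
        ripples = ripples)
    }
  }
  structure(list(events = events,
                 incidence = nrow(events) / (rec$duration / 60),
                 sd_spw = s, spw_band = spw_band, ripple_band = ripple_band),
            class = "spwr_set")
}

#' @export
print.spwr_set <- function(x, ...) {
  cat(sprintf("SPW-R detection: %d events, incidence %.3g /min\n",
              nrow(x$events), x$incidence))
  if (nrow(x$events))
    cat(sprintf("  Amp median %.4g µV; Duration median %.3g ms; R/SPW median %g\n",
                stats::median(x$events$amp_uV), stats::median(x$events$duration_ms),
                stats::median(x$events$ripples)))
  invisible(x)
}

#' Group summary (median ± IQR convention)
#'
#' Summarizes one metric across recordings the way slice electrophysiology
#' results are reported: median, interquartile range (75th minus 25th
#' percentile) and the min-max range, plus, for burst analyses, the fraction
#' of recordings expressing events at all.
#'
#' @param values numeric metric values, one per recording.
#' @param with_events optional logical vector (one per recording): whether
#'   the recording expressed any events.
#' @return An object of class `group_summary`: `median`, `p25`, `p75`,
#'   `iqr`, `min`, `max`, `n`, `fraction_with_events`.
#' @export
summarize_group <- function(values, with_events = NULL) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    median = q[2L], p25 = q[1L], p75 = q[3L], iqr = q[3L] - q[1L],
    min = min(values), max = max(values), n = length(values),
    fraction_with_events = if (is.null(with_events)) NA_real_ else mean(with_events)
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d: median %.4g, IQR %.4g (p25 %.4g, p75 %.4g), range [%.4g, %.4g]\n",
              x$n, x$median, x$iqr, x$p25, x$p75, x$min, x$max))
  if (!is.na(x$fraction_with_events))
    cat(sprintf("  fraction of recordings with events: %.2f\n", x$fraction_with_events))
  invisible(x)
}

#' Score detected events against ground truth
#'
#' Greedy one-to-one matching of detected to ground-truth event times within
#' a tolerance, yielding precision, recall and F1 — the scoring used to
#' validate the detectors on synthetic recordings.
#'
#' @param detected,truth numeric vectors of event times (s).
#' @param tol matching tolerance in seconds (default ±50 ms).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
score_events <- function(detected, truth, tol = 0.05) {
  detected <- sort(detected)
  truth <- sort(truth)
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    cand <- which(!used & abs(detected - t) <= tol)
    if (length(cand)) {
      used[cand[which.min(abs(detected[cand] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!used)
  fn <- length(truth) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) 2 * precision * recall / (precision + recall)
        else if (tp + fp + fn == 0L) NA_real_ else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall, f1 = f1)
}
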