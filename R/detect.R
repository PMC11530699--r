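highpass4 <- function(x, fs_hz, cutoff_hz) {
  butter_filtfilt(x, cutoff_hz / (fs_hz / 2), "high")
}

#' Estimate the noise standard deviation of an ROI series
#'
#' Finds a spike-free section of at least `window_s` seconds, high-pass
#' filters it at `cutoff_hz` (default 50 Hz, removing slow subthreshold
#' oscillations) and returns the standard deviation of the filtered values.
#' This figure defines one SNR unit for the series. The window is chosen
#' automatically as the minimum-variance `window_s` stretch of the series
#' after a 2 Hz high-pass (a spike-free stretch has the least variance);
#' supply `window_ms = c(t0, t1)` to override manually.
#'
#' @param series A `roi_series`, [sampled_series()] or numeric vector.
#' @param fs_hz Sampling rate in Hz (required for a bare numeric vector).
#' @param window_s Minimum window length in seconds (default 2).
#' @param cutoff_hz Noise high-pass cutoff in Hz (default 50).
#' @param window_ms Optional manual window `c(start_ms, end_ms)`.
#' @return Noise standard deviation (one SNR unit).
#' @export
estimate_noise <- function(series, fs_hz = NULL, window_s = 2,
                           cutoff_hz = 50, window_ms = NULL) {
  xs <- series_values(series, fs_hz)
  x <- xs$x; fs <- xs$fs; t <- xs$t
  n_win <- round(window_s * fs)
  if (length(x) < n_win) {
    stop(sprintf("series shorter than the %g s noise window", window_s),
         call. = FALSE)
  }
  h <- highpass4(x, fs, cutoff_hz)
  if (!is.null(window_ms)) {
    sel <- t >= window_ms[1] & t <= window_ms[2]
    if (sum(sel) < n_win) stop("manual window shorter than window_s", call. = FALSE)
    return(stats::sd(h[sel]))
  }
  # automatic: minimum-variance window on the 2 Hz high-passed series
  slow <- highpass4(x, fs, 2)
  starts <- seq(1, length(x) - n_win + 1, by = max(1, round(n_win / 4)))
  vars <- vapply(starts, function(i) stats::var(slow[i:(i + n_win - 1)]), 1.0)
  i0 <- starts[which.min(vars)]
  stats::sd(h[i0:(i0 + n_win - 1)])
}

series_values <- function(series, fs_hz) {
  if (inherits(series, "sampled_series")) {
    list(x = series$value, t = series$time_ms,
         fs = if (is.null(fs_hz)) period_to_rate(series$config$t_sample) else fs_hz)
  } else if (inherits(series, "roi_series") || is.data.frame(series)) {
    fs <- if (!is.null(attr(series, "rate_hz"))) attr(series, "rate_hz") else fs_hz
    if (is.null(fs)) fs <- period_to_rate(stats::median(diff(series$time_ms)))
    list(x = series$value, t = series$time_ms, fs = fs)
  } else {
    if (is.null(fs_hz)) stop("fs_hz required for a bare numeric series", call. = FALSE)
    list(x = as.numeric(series), t = (seq_along(series) - 1) * rate_to_period(fs_hz),
         fs = fs_hz)
  }
}

#' Detect putative spiking events
#'
#' The series is high-pass filtered at `prefilter_hz` (default 2 Hz, removing
#' high-amplitude low-frequency oscillations), divided by the noise standard
#' deviation, and scanned for local maxima exceeding `threshold` SNR units;
#' maxima closer than `refractory_ms` to an accepted event are suppressed.
#' Events inside `burn_in_ms` of either end of the series are discarded
#' (zero-phase filter edges are unreliable there).
#'
#' @param series A `roi_series`, [sampled_series()] or numeric vector.
#' @param noise_sd Noise standard deviation (one SNR unit), > 0; see
#'   [estimate_noise()].
#' @param fs_hz Sampling rate in Hz if not discoverable from `series`.
#' @param threshold Detection threshold in SNR units (default 5).
#' @param refractory_ms Minimum spacing between events (default 5 ms).
#' @param prefilter_hz Detection high-pass cutoff (default 2 Hz).
#' @param burn_in_ms Edge exclusion (default 0; set a few hundred ms for
#'   short heavily filtered records).
#' @return Data frame with `time_ms` and `snr`, one row per event.
#' @export
detect_spikes <- function(series, noise_sd, fs_hz = NULL, threshold = 5,
                          refractory_ms = 5, prefilter_hz = 2,
                          burn_in_ms = 0) {
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be > 0", call. = FALSE)
  }
  xs <- series_values(series, fs_hz)
  snr <- highpass4(xs$x, xs$fs, prefilter_hz) / noise_sd
  n <- length(snr)
  if (!is.finite(threshold)) {
    return(data.frame(time_ms = numeric(0), snr = numeric(0)))
  }
  is_peak <- c(FALSE, diff(sign(diff(snr))) == -2, FALSE)
  cand <- which(is_peak & snr > threshold)
  cand <- cand[xs$t[cand] >= xs$t[1] + burn_in_ms &
                 xs$t[cand] <= xs$t[n] - burn_in_ms]
  cand <- cand[order(xs$t[cand])]
  keep <- integer(0); last <- -Inf
  for (i in cand) {
    if (xs$t[i] - last > refractory_ms) {
      keep <- c(keep, i)
      last <- xs$t[i]
    }
  }
  data.frame(time_ms = xs$t[keep], snr = snr[keep])
}

#' Match events against a second series
#'
#' For each event, reports the highest SNR of the comparison series within a
#' window of `window_ms` (default 30 ms) centered on the event peak time.
#' Windows reaching beyond the comparison series are clipped with a warning.
#'
#' @param events Data frame from [detect_spikes()] (needs `time_ms`, `snr`).
#' @param series_b Comparison series (same time origin).
#' @param noise_sd_b Noise standard deviation of the comparison series.
#' @param fs_hz_b Sampling rate of the comparison series if not discoverable.
#' @param window_ms Full window width in ms (default 30).
#' @param prefilter_hz Detection high-pass applied to the comparison series.
#' @return `events` with added columns `snr_b` (peak comparison SNR in the
#'   window) and `ratio` (`snr / snr_b`).
#' @export
match_events <- function(events, series_b, noise_sd_b, fs_hz_b = NULL,
                         window_ms = 30, prefilter_hz = 2) {
  stopifnot(is.data.frame(events), noise_sd_b > 0)
  xs <- series_values(series_b, fs_hz_b)
  snr_b <- highpass4(xs$x, xs$fs, prefilter_hz) / noise_sd_b
  half <- window_ms / 2
  if (nrow(events) &&
      (min(events$time_ms) - half < xs$t[1] ||
       max(events$time_ms) + half > xs$t[length(xs$t)])) {
    warning("match window extends beyond the comparison series; clipped")
  }
  events$snr_b <- vapply(events$time_ms, function(te) {
    sel <- xs$t >= te - half & xs$t <= te + half
    if (!any(sel)) NA_real_ else max(snr_b[sel])
  }, 1.0)
  events$ratio <- events$snr / events$snr_b
  events
}

#' Compare paired event SNRs between two sensors
#'
#' Two-sided Wilcoxon rank-sum test for equal medians on the paired event
#' SNR columns produced by [match_events()], plus summary medians and the
#' median paired gain.
#'
#' @param matched Data frame from [match_events()].
#' @return List with `median_a`, `median_b`, `median_ratio`, `p_value`, `n`.
#' @export
compare_event_snr <- function(matched) {
  stopifnot(all(c("snr", "snr_b") %in% names(matched)))
  ok <- stats::complete.cases(matched[, c("snr", "snr_b")])
  a <- matched$snr[ok]; b <- matched$snr_b[ok]
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  list(median_a = stats::median(a), median_b = stats::median(b),
       median_ratio = stats::median(a / b), p_value = wt$p.value,
       n = length(a))
}

#' Stimulus windows of a current-step protocol
#'
#' 200-ms constant-current steps from +600 pA down to 0 pA in 40 pA
#' decrements (16 steps), spaced so that the 100 ms flanking windows used by
#' [pulse_snr()] never overlap a neighboring pulse.
#'
#' @param start_ms Start of the first pulse (default 500 ms).
#' @param gap_ms Gap between consecutive pulses (default 300 ms, >= 200).
#' @return Data frame with `start_ms`, `duration_ms`, `amplitude_pa`.
#' @export
current_step_protocol <- function(start_ms = 500, gap_ms = 300) {
  stopifnot(gap_ms >= 200)
  amps <- seq(600, 0, by = -40)
  data.frame(start_ms = start_ms + (seq_along(amps) - 1) * (200 + gap_ms),
             duration_ms = 200,
             amplitude_pa = amps)
}

#' Pulse-response SNR for a current-step protocol
#'
#' For each pulse window, the GEVI pulse amplitude is the difference between
#' the mean signal during the pulse and the mean over the two 100 ms flanks
#' immediately before and after it; dividing by the noise standard deviation
#' converts it to SNR units.
#'
#' @param series A `roi_series`, [sampled_series()] or numeric vector.
#' @param pulses Data frame with `start_ms` and `duration_ms` (e.g. from
#'   [current_step_protocol()]).
#' @param noise_sd Noise standard deviation (one SNR unit).
#' @param fs_hz Sampling rate if not discoverable from `series`.
#' @return `pulses` with an added `pulse_snr` column.
#' @export
pulse_snr <- function(series, pulses, noise_sd, fs_hz = NULL) {
  stopifnot(noise_sd > 0, all(c("start_ms", "duration_ms") %in% names(pulses)))
  xs <- series_values(series, fs_hz)
  ends <- pulses$start_ms + pulses$duration_ms
  if (any(pulses$start_ms[-1] < ends[-length(ends)] + 200)) {
    stop("pulses too close: 100 ms flanks would overlap a neighboring pulse",
         call. = FALSE)
  }
  if (min(pulses$start_ms) - 100 < xs$t[1] ||
      max(ends) + 100 > xs$t[length(xs$t)]) {
    stop("series does not cover the 100 ms flanks of every pulse", call. = FALSE)
  }
  pulses$pulse_snr <- vapply(seq_len(nrow(pulses)), function(i) {
    s <- pulses$start_ms[i]; e <- ends[i]
    inside <- xs$t >= s & xs$t < e
    flank <- (xs$t >= s - 100 & xs$t < s) | (xs$t >= e & xs$t < e + 100)
    (mean(xs$x[inside]) - mean(xs$x[flank])) / noise_sd
  }, 1.0)
  pulses
}
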