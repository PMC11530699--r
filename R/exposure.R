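#' Per-pixel exposure configuration
#'
#' A pixel integrates photons over a box window of duration `t_exp` (ms) and
#' is read out every `t_sample` (ms), with its sampling grid shifted by the
#' phase offset `delta` (ms). Sample `m` integrates the window
#' `[delta + m*t_sample - t_exp, delta + m*t_sample)` and is timestamped at
#' the end of its exposure window (`delta + m*t_sample`), the instant the
#' pixel is read out. Back-to-back exposure (`t_sample == t_exp`) is the
#' default and matches how staggered and multi-speed layouts are operated.
#'
#' Physical pixels have `t_sample >= t_exp` (a new exposure starts only after
#' the previous one is read out); configurations with `t_sample < t_exp`
#' describe overlapping windows and are permitted as mathematical references
#' (e.g. the single faster pixel that a staggered ensemble is equivalent to).
#'
#' @param t_exp Exposure duration in ms, > 0.
#' @param delta Phase offset in ms, in `[0, t_sample)`.
#' @param t_sample Sample period in ms, > 0 (default `t_exp`).
#' @return An object of class `exposure_config`.
#' @export
exposure_config <- function(t_exp, delta = 0, t_sample = t_exp) {
  stopifnot(is.numeric(t_exp), is.numeric(delta), is.numeric(t_sample))
  if (t_exp <= 0 || t_sample <= 0) {
    stop("need t_exp > 0 and t_sample > 0", call. = FALSE)
  }
  if (delta < 0 || delta >= t_sample) {
    stop("need 0 <= delta < t_sample", call. = FALSE)
  }
  structure(list(t_exp = t_exp, delta = delta, t_sample = t_sample),
            class = "exposure_config")
}

#' @export
print.exposure_config <- function(x, ...) {
  cat(sprintf("exposure_config: t_exp = %g ms, delta = %g ms, t_sample = %g ms (%g Hz)\n",
              x$t_exp, x$delta, x$t_sample, period_to_rate(x$t_sample)))
  invisible(x)
}

check_on_grid <- function(config, dt) {
  ok <- is_grid_multiple(config$t_exp, dt) &&
    is_grid_multiple(config$delta, dt) &&
    is_grid_multiple(config$t_sample, dt)
  if (!ok) {
    stop(sprintf("exposure config (t_exp=%g, delta=%g, t_sample=%g) is not aligned to the %g ms fine grid",
                 config$t_exp, config$delta, config$t_sample, dt), call. = FALSE)
  }
  invisible(TRUE)
}

#' Discrete exposure kernel
#'
#' The box exposure of duration `t_exp` discretized on the fine grid: a
#' kernel of `t_exp/dt` taps, each of weight `dt`, so that convolving a
#' photoelectron-rate trace (e-/ms) with the kernel yields electron counts
#' (the weights sum to `t_exp`).
#'
#' @param config An [exposure_config()].
#' @param dt Fine grid step in ms; `t_exp` must be a multiple of it.
#' @return Numeric vector of integration weights.
#' @export
exposure_kernel <- function(config, dt) {
  stopifnot(inherits(config, "exposure_config"))
  check_on_grid(config, dt)
  rep(dt, round(config$t_exp / dt))
}

#' Sampling matrix of one exposure configuration
#'
#' Builds the matrix `E` that maps a fine-grid photoelectron-rate signal of
#' length `l_fine` to the pixel's integrated samples. Row `m` integrates
#' the fine-grid window `[delta + m*t_sample - t_exp, delta + m*t_sample)`;
#' rows are shifted copies of the box kernel and each sums to `t_exp`.
#' Rows run over every `m` whose window lies inside the grid: for
#' back-to-back exposure (`t_sample == t_exp`) that is `m = 1, ...,
#' floor((l_fine*dt - delta)/t_sample)`; for overlapping sampling
#' (`t_sample < t_exp`, not produced by the standard layouts) the first rows
#' would reach before time 0 and are dropped.
#'
#' @param config An [exposure_config()].
#' @param l_fine Number of fine-grid bins.
#' @param dt Fine grid step in ms.
#' @return A dense `M x l_fine` matrix with attribute `sample_times_ms`
#'   (end-of-exposure timestamps).
#' @export
build_sampling_matrix <- function(config, l_fine, dt) {
  stopifnot(inherits(config, "exposure_config"))
  check_on_grid(config, dt)
  total <- l_fine * dt
  if (total < config$t_sample + config$delta) {
    stop("fine grid too short: need l_fine*dt >= t_sample + delta", call. = FALSE)
  }
  m_min <- max(1L, as.integer(ceiling((config$t_exp - config$delta) / config$t_sample - 1e-9)))
  m_max <- as.integer(floor((total - config$delta) / config$t_sample + 1e-9))
  if (m_max < m_min) stop("no complete exposure window fits the grid", call. = FALSE)
  ms <- m_min:m_max
  k <- round(config$t_exp / dt)
  ends <- round((config$delta + ms * config$t_sample) / dt)
  e <- matrix(0, length(ms), l_fine)
  for (i in seq_along(ms)) {
    e[i, (ends[i] - k + 1):ends[i]] <- dt
  }
  attr(e, "sample_times_ms") <- config$delta + ms * config$t_sample
  e
}

# Noiseless samples of a fine-grid trace under config, via cumulative sums
# (equivalent to build_sampling_matrix %*% values but O(L)).
integrate_windows <- function(values, dt, config) {
  total <- length(values) * dt
  m_min <- max(1L, as.integer(ceiling((config$t_exp - config$delta) / config$t_sample - 1e-9)))
  m_max <- as.integer(floor((total - config$delta) / config$t_sample + 1e-9))
  if (m_max < m_min) stop("no complete exposure window fits the trace", call. = FALSE)
  ms <- m_min:m_max
  k <- round(config$t_exp / dt)
  ends <- round((config$delta + ms * config$t_sample) / dt)
  cs <- c(0, cumsum(values)) * dt
  list(times = config$delta + ms * config$t_sample,
       electrons = cs[ends + 1] - cs[ends - k + 1])
}

#' Noise model parameters
#'
#' Shot noise is Poisson with rate equal to the electron count at the pixel
#' (signal plus baseline). Read noise is zero-mean Gaussian whose variance
#' scales inversely with the exposure duration, `N0 / t_exp`, reflecting the
#' thermal-noise bandwidth of the readout chain; `n0` therefore has units of
#' electrons^2 * ms. Use [calibrate_read_noise()] to derive `n0` from an rms
#' read noise quoted at a reference exposure.
#'
#' @param baseline_rate Baseline fluorescence photoelectron rate F in e-/ms.
#' @param n0 Read-noise density in e-^2 * ms (default: 2.6 e- rms at the
#'   0.9 ms readout period).
#' @param shot,read Logical flags enabling each noise source.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(baseline_rate = 20,
                         n0 = calibrate_read_noise(2.6, 0.9),
                         shot = TRUE, read = TRUE) {
  stopifnot(baseline_rate >= 0, n0 >= 0)
  structure(list(baseline_rate = baseline_rate, n0 = n0,
                 shot = isTRUE(shot), read = isTRUE(read)),
            class = "noise_params")
}

#' Calibrate the read-noise density from a quoted rms figure
#'
#' Under the thermal-noise model the per-sample read variance is
#' `n0 / t_exp`, so a sensor quoting `rms_e` electrons rms at a reference
#' exposure `t_ref_ms` implies `n0 = rms_e^2 * t_ref_ms`.
#'
#' @param rms_e Read noise in electrons rms at the reference exposure.
#' @param t_ref_ms Reference exposure/readout period in ms (default 0.9 ms,
#'   a typical column-readout period).
#' @return Read-noise density in e-^2 * ms.
#' @export
calibrate_read_noise <- function(rms_e, t_ref_ms = 0.9) {
  stopifnot(rms_e >= 0, t_ref_ms > 0)
  rms_e^2 * t_ref_ms
}

#' Timestamped samples of one pixel (or pixel group)
#'
#' @param time_ms Strictly increasing end-of-exposure timestamps.
#' @param value Sample values (electrons unless noted by `units`).
#' @param config The generating [exposure_config()].
#' @param units Unit tag, default `"electrons"`.
#' @return An object of class `sampled_series`.
#' @export
sampled_series <- function(time_ms, value, config, units = "electrons") {
  stopifnot(length(time_ms) == length(value), all(diff(time_ms) > 0))
  structure(list(time_ms = as.numeric(time_ms), value = as.numeric(value),
                 config = config, units = units),
            class = "sampled_series")
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf("sampled_series: %d samples at %g Hz (t_exp = %g ms, delta = %g ms), units = %s\n",
              length(x$value), period_to_rate(x$config$t_sample),
              x$config$t_exp, x$config$delta, x$units))
  invisible(x)
}

#' @export
as.data.frame.sampled_series <- function(x, ...) {
  data.frame(time_ms = x$time_ms, value = x$value)
}

draw_noise <- function(means, noise, t_exp) {
  if (any(means < -1e-9)) {
    stop("negative electron mean: trace must be a non-negative rate", call. = FALSE)
  }
  means[means < 0] <- 0
  out <- means
  if (!is.null(noise) && noise$shot) out <- stats::rpois(length(means), means)
  if (!is.null(noise) && noise$read && noise$n0 > 0) {
    out <- out + stats::rnorm(length(means), 0, sqrt(noise$n0 / t_exp))
  }
  out
}

#' Sample a fine-grid trace with one pixel
#'
#' Integrates the trace over each exposure window (electron counts), then
#' applies shot noise (Poisson with mean equal to the electron count) and
#' read noise (zero-mean Gaussian with variance `n0 / t_exp`) according to
#' `noise`. If `noise` carries a positive `baseline_rate` and the trace is a
#' pure dF/F-free signal, fold the baseline into the trace beforehand (the
#' usual route is [spike_train()], which already includes it); this function
#' treats the trace as the complete photoelectron rate at the pixel.
#'
#' @param trace A [fine_grid_trace()] in e-/ms units.
#' @param config An [exposure_config()] aligned to the trace grid.
#' @param noise A [noise_params()] or `NULL` for noiseless sampling.
#' @param seed Optional integer seed for reproducibility.
#' @return A [sampled_series()] in electrons.
#' @export
sample_pixel <- function(trace, config, noise = NULL, seed = NULL) {
  stopifnot(inherits(trace, "fine_grid_trace"), inherits(config, "exposure_config"))
  if (trace$units != "e_per_ms") {
    stop("trace must be in e_per_ms units (fold dF/F through a baseline rate first)",
         call. = FALSE)
  }
  check_on_grid(config, trace$dt)
  w <- integrate_windows(trace$values, trace$dt, config)
  if (!is.null(seed)) set.seed(seed)
  sampled_series(w$times, draw_noise(w$electrons, noise, config$t_exp), config)
}

#' Sample the average of many identical pixels sharing one trace
#'
#' The mean of `n_pixels` independent pixels that view the same
#' photoelectron-rate trace has an exact sufficient statistic: the summed
#' shot noise is Poisson with `n_pixels` times the single-pixel mean, and the
#' averaged read noise is Gaussian with variance `n0 / t_exp / n_pixels`.
#' This samples that statistic directly, so large regions of interest can be
#' simulated without materializing per-pixel arrays.
#'
#' @inheritParams sample_pixel
#' @param n_pixels Number of pixels averaged, >= 1.
#' @return A [sampled_series()] whose values are mean electrons per pixel.
#' @export
sample_roi_series <- function(trace, config, noise = NULL, n_pixels = 1,
                              seed = NULL) {
  stopifnot(inherits(trace, "fine_grid_trace"), inherits(config, "exposure_config"),
            n_pixels >= 1)
  check_on_grid(config, trace$dt)
  w <- integrate_windows(trace$values, trace$dt, config)
  if (any(w$electrons < -1e-9)) stop("negative electron mean", call. = FALSE)
  mu <- pmax(w$electrons, 0)
  if (!is.null(seed)) set.seed(seed)
  out <- mu
  if (!is.null(noise) && noise$shot) {
    out <- stats::rpois(length(mu), n_pixels * mu) / n_pixels
  }
  if (!is.null(noise) && noise$read && noise$n0 > 0) {
    out <- out + stats::rnorm(length(mu), 0,
                              sqrt(noise$n0 / config$t_exp / n_pixels))
  }
  sampled_series(w$times, out, config)
}
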