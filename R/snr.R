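#' Peak sampled response of a GEVI spike at a given exposure
#'
#' The spike's photoelectron-rate component is
#' `baseline_rate * peak_dff * w(t)` with `w` the normalized waveform; the
#' pixel output is its convolution with the box exposure. This returns the
#' maximum of that convolution over all window placements (best-phase
#' alignment), in electrons. It is non-decreasing in `t_exp` and saturates at
#' the total spike area once the window covers the whole transient.
#'
#' @param params A [gevi_spike_params()] object.
#' @param baseline_rate Baseline rate F in e-/ms (spike amplitude is
#'   `peak_dff * F`).
#' @param t_exp Exposure duration in ms (>= `dt`).
#' @param dt Fine evaluation grid in ms (default 0.025, dividing the
#'   canonical 1.25 ms exposure).
#' @return Peak response in electrons.
#' @export
peak_response <- function(params, baseline_rate, t_exp, dt = 0.025) {
  stopifnot(inherits(params, "gevi_spike_params"), baseline_rate >= 0)
  if (t_exp < dt) stop("t_exp must be at least the fine grid step", call. = FALSE)
  span_l <- 12 * params$tau_rs
  span_r <- 12 * params$tau_fs + t_exp
  t <- seq(-span_l, span_r, by = dt)
  v <- baseline_rate * spike_waveform(t, params)
  k <- round(t_exp / dt)
  cs <- c(0, cumsum(v)) * dt
  n <- length(cs)
  max(cs[(k + 1):n] - cs[1:(n - k)])
}

#' Analytic peak pixel SNR at a given exposure
#'
#' The peak-sample signal is `S = max(y)^2` with `max(y)` from
#' [peak_response()]; the noise power is the sum of the read-noise variance
#' `n0 / t_exp`, the signal's own shot noise `max(y)` and the baseline shot
#' noise `F * t_exp`:
#' \deqn{SNR = \frac{\max(y)}{\sqrt{N_0/T_E + \max(y) + F\,T_E}}.}
#' With `simplified = TRUE` the signal shot-noise term is dropped, the
#' approximation valid when the baseline dominates the transient
#' (`F*T_E >> max(y)`).
#'
#' @param params A [gevi_spike_params()] object.
#' @param noise A [noise_params()] (its `baseline_rate` is F).
#' @param t_exp Exposure duration in ms.
#' @param simplified Drop the `max(y)` shot term (baseline-dominated form).
#' @param dt Fine evaluation grid in ms.
#' @param signal_rate Rate scale of the spike amplitude (defaults to the
#'   noise baseline F, i.e. a transient of `peak_dff * F`); passing it
#'   separately decouples the signal brightness from the shot-noise baseline.
#' @return Dimensionless SNR (amplitude over rms noise).
#' @export
snr_at_exposure <- function(params, noise, t_exp, simplified = FALSE,
                            dt = 0.025, signal_rate = noise$baseline_rate) {
  stopifnot(inherits(noise, "noise_params"))
  my <- peak_response(params, signal_rate, t_exp, dt = dt)
  denom <- noise$n0 / t_exp + noise$baseline_rate * t_exp +
    if (simplified) 0 else my
  if (denom <= 0) {
    stop("SNR undefined: zero noise (set n0 or baseline_rate > 0)", call. = FALSE)
  }
  my / sqrt(denom)
}

#' SNR-versus-exposure curve
#'
#' Evaluates [snr_at_exposure()] on an exposure grid and records the noise
#' components per point. With `normalize = TRUE` the SNR column is divided by
#' its maximum (for comparing indicators of different brightness).
#'
#' @param params A [gevi_spike_params()] object.
#' @param noise A [noise_params()].
#' @param t_grid Exposure grid in ms (default 0.5 to 20 ms, step 0.1 ms).
#' @param normalize Scale the curve to a maximum of 1.
#' @param dt Fine evaluation grid in ms.
#' @inheritParams snr_at_exposure
#' @return A data frame of class `snr_curve` with columns `t_exp_ms`, `snr`,
#'   `signal_peak` (electrons), `n_shot`, `n_read` (variances), and attribute
#'   `argmax_ms`.
#' @export
snr_curve <- function(params, noise, t_grid = seq(0.5, 20, by = 0.1),
                      normalize = FALSE, dt = 0.025,
                      signal_rate = noise$baseline_rate) {
  stopifnot(all(diff(t_grid) > 0))
  my <- vapply(t_grid, function(te) peak_response(params, signal_rate,
                                                  te, dt = dt), 1.0)
  n_read <- noise$n0 / t_grid
  n_shot <- my + noise$baseline_rate * t_grid
  snr <- my / sqrt(n_read + n_shot)
  if (normalize) snr <- snr / max(snr)
  out <- data.frame(t_exp_ms = t_grid, snr = snr, signal_peak = my,
                    n_shot = n_shot, n_read = n_read)
  attr(out, "argmax_ms") <- t_grid[which.max(snr)]
  class(out) <- c("snr_curve", "data.frame")
  out
}

#' Exposure duration maximizing the analytic SNR
#'
#' Grid search over `t_grid`; ties break toward the smaller exposure. If the
#' curve has more than one interior local maximum a warning is emitted and
#' the global argmax is returned.
#'
#' @inheritParams snr_curve
#' @return Optimal exposure in ms.
#' @export
optimal_exposure <- function(params, noise, t_grid = seq(0.5, 20, by = 0.1),
                             dt = 0.025, signal_rate = noise$baseline_rate) {
  cv <- snr_curve(params, noise, t_grid = t_grid, dt = dt,
                  signal_rate = signal_rate)
  s <- cv$snr
  # interior local maxima with a tolerance against grid-quantization ripple
  d <- diff(s)
  peaks <- which(d[-length(d)] > 1e-9 & d[-1] < -1e-9) + 1
  if (length(peaks) > 1) {
    warning("SNR curve is not unimodal on the grid; returning the global argmax")
  }
  t_grid[which.max(s)]
}
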