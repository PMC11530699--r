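#' Parameters of a double-exponential GEVI spike waveform
#'
#' A fluorescence transient reported by a genetically encoded voltage
#' indicator (GEVI) during an action potential is modelled as a pair of
#' double-exponential branches meeting at the peak (taken as time 0):
#' a rising branch \eqn{A_R e^{t/\tau_{Rf}} + B_R e^{t/\tau_{Rs}}} for
#' \eqn{t < 0} and a falling branch
#' \eqn{A_F e^{-t/\tau_{Ff}} + B_F e^{-t/\tau_{Fs}}} for \eqn{t \ge 0}.
#' Each branch mixes a fast and a slow time scale.
#'
#' The constructor enforces continuity at the peak by rescaling the falling
#' amplitudes so that \eqn{A_R + B_R = A_F + B_F}, and then normalizes all
#' four amplitudes so that the waveform maximum (attained at t = 0, since
#' both branches decay away from the peak) equals `peak_dff`.
#'
#' @param tau_rf,tau_rs Fast and slow rise time constants (ms), > 0.
#' @param tau_ff,tau_fs Fast and slow fall time constants (ms), > 0.
#' @param a_r,b_r Rising-branch amplitudes (dimensionless, >= 0, not both 0).
#' @param a_f,b_f Falling-branch amplitudes before continuity rescaling.
#' @param peak_dff Peak fractional fluorescence change dF/F (e.g. 0.10).
#' @return An object of class `gevi_spike_params`.
#' @seealso [gevi_preset()], [spike_waveform()], [half_width()]
#' @export
gevi_spike_params <- function(tau_rf, tau_rs, tau_ff, tau_fs,
                              a_r, b_r, a_f, b_f, peak_dff = 0.1) {
  taus <- c(tau_rf = tau_rf, tau_rs = tau_rs, tau_ff = tau_ff, tau_fs = tau_fs)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    stop("all time constants must be finite and > 0", call. = FALSE)
  }
  amps <- c(a_r = a_r, b_r = b_r, a_f = a_f, b_f = b_f)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("all amplitudes must be finite and >= 0", call. = FALSE)
  }
  if (a_r + b_r <= 0 || a_f + b_f <= 0) {
    stop("each branch needs at least one positive amplitude", call. = FALSE)
  }
  if (!is.finite(peak_dff) || peak_dff <= 0) {
    stop("peak_dff must be > 0", call. = FALSE)
  }
  # continuity at t = 0, then peak normalization
  s <- (a_r + b_r) / (a_f + b_f)
  a_f <- a_f * s
  b_f <- b_f * s
  z <- peak_dff / (a_r + b_r)
  out <- list(
    tau_rf = tau_rf, tau_rs = tau_rs, tau_ff = tau_ff, tau_fs = tau_fs,
    a_r = a_r * z, b_r = b_r * z, a_f = a_f * z, b_f = b_f * z,
    peak_dff = peak_dff
  )
  class(out) <- "gevi_spike_params"
  out
}

#' @export
print.gevi_spike_params <- function(x, ...) {
  cat("GEVI spike parameters (double exponential)\n")
  cat(sprintf("  rise: %.4g*exp(t/%.3g) + %.4g*exp(t/%.3g)   [t < 0, ms]\n",
              x$a_r, x$tau_rf, x$b_r, x$tau_rs))
  cat(sprintf("  fall: %.4g*exp(-t/%.3g) + %.4g*exp(-t/%.3g) [t >= 0, ms]\n",
              x$a_f, x$tau_ff, x$b_f, x$tau_fs))
  cat(sprintf("  peak dF/F: %.3g   half-width: %.3g ms\n",
              x$peak_dff, half_width(x)))
  invisible(x)
}

#' Named GEVI waveform presets
#'
#' Three named presets with two-time-scale kinetics (fast time constant well
#' below the slow one on each branch). The indicator papers these presets are
#' named after report their kinetics in their own publications;
#' exact time constants are not printed here, so the preset values below are
#' package defaults chosen to reproduce the published qualitative behaviour:
#' the `"asap3"` preset has a spike full-width at half-maximum of ~6 ms, the
#' figure reported for cultured-neuron action potentials with that indicator,
#' while `"archon"` and `"voltron"` are faster.
#'
#' @param name One of `"asap3"`, `"archon"`, `"voltron"`.
#' @param peak_dff Peak dF/F of the normalized spike (default 0.10).
#' @return A [gevi_spike_params()] object.
#' @export
gevi_preset <- function(name = c("asap3", "archon", "voltron"),
                        peak_dff = 0.1) {
  name <- match.arg(name)
  p <- switch(name,
    asap3   = list(1.3, 7.9, 5.9, 21.0, 0.75, 0.25, 0.85, 0.15),
    archon  = list(0.6, 3.2, 2.1, 9.0, 0.82, 0.18, 0.87, 0.13),
    voltron = list(0.6, 3.5, 2.4, 10.0, 0.80, 0.20, 0.85, 0.15)
  )
  gevi_spike_params(p[[1]], p[[2]], p[[3]], p[[4]],
                    p[[5]], p[[6]], p[[7]], p[[8]], peak_dff = peak_dff)
}

#' Evaluate the GEVI spike waveform
#'
#' Returns the dF/F value of the double-exponential spike at time(s) `t`
#' relative to the spike peak. The rising branch is used for `t < 0`, the
#' falling branch for `t >= 0`; the two meet at `peak_dff` at `t = 0`.
#'
#' @param t Time(s) in ms relative to the spike peak.
#' @param params A [gevi_spike_params()] object.
#' @return dF/F values, same length as `t`.
#' @export
spike_waveform <- function(t, params) {
  stopifnot(inherits(params, "gevi_spike_params"))
  ifelse(t < 0,
         params$a_r * exp(t / params$tau_rf) + params$b_r * exp(t / params$tau_rs),
         params$a_f * exp(-t / params$tau_ff) + params$b_f * exp(-t / params$tau_fs))
}

#' Full width at half maximum of a GEVI spike
#'
#' Found numerically on a time grid of step `dt` (default 0.01 ms) spanning
#' many multiples of the slowest time constants on either side of the peak.
#'
#' @param params A [gevi_spike_params()] object.
#' @param dt Grid step in ms (must be <= 0.01).
#' @return Half-width in ms.
#' @export
half_width <- function(params, dt = 0.01) {
  stopifnot(inherits(params, "gevi_spike_params"), dt <= 0.01, dt > 0)
  t <- seq(-12 * params$tau_rs, 12 * params$tau_fs, by = dt)
  v <- spike_waveform(t, params)
  above <- which(v >= params$peak_dff / 2)
  t[above[length(above)]] - t[above[1]]
}

#' Fluorescence trace on a fine simulation grid
#'
#' Container for a regularly sampled ground-truth signal. Bin `i` carries the
#' signal over `[t0 + (i-1)*dt, t0 + i*dt)`. The unit tag is explicit:
#' `"e_per_ms"` for a photoelectron rate (integrating over an exposure window
#' yields electrons) or `"dff"` for a fractional fluorescence change.
#'
#' @param values Numeric vector (length >= 1).
#' @param dt Fine grid step in ms, > 0.
#' @param t0 Time origin in ms.
#' @param units `"e_per_ms"` or `"dff"`.
#' @return An object of class `fine_grid_trace`.
#' @export
fine_grid_trace <- function(values, dt, t0 = 0, units = c("e_per_ms", "dff")) {
  units <- match.arg(units)
  stopifnot(is.numeric(values), length(values) >= 1, dt > 0)
  structure(list(values = as.numeric(values), dt = dt, t0 = t0, units = units),
            class = "fine_grid_trace")
}

#' @export
print.fine_grid_trace <- function(x, ...) {
  cat(sprintf("fine_grid_trace: %d points, dt = %g ms, t0 = %g ms, units = %s\n",
              length(x$values), x$dt, x$t0, x$units))
  invisible(x)
}

#' Bin start times of a fine-grid trace
#' @param trace A [fine_grid_trace()].
#' @return Numeric vector of bin start times in ms.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "fine_grid_trace"))
  trace$t0 + (seq_along(trace$values) - 1) * trace$dt
}

#' Generate a spike train riding on a constant baseline
#'
#' Superimposes spike waveforms at the given peak times on a constant
#' baseline photoelectron rate:
#' `trace = baseline_rate * (1 + sum of spikes in dF/F)`. Overlapping spikes
#' add linearly. By default spikes are generated positive-going; indicators
#' with negative-going transients (the raw polarity of some voltage sensors)
#' can be simulated with `sign = -1`, but detection downstream always assumes
#' the positive-going convention, matching the usual practice of inverting
#' such series before analysis.
#'
#' @param spike_times Peak times in ms, within `[0, duration)`.
#' @param params A [gevi_spike_params()] object.
#' @param baseline_rate Baseline photoelectron rate in e-/ms, >= 0.
#' @param duration Trace duration in ms.
#' @param dt Fine grid step in ms; must be <= 0.25 ms so the fastest time
#'   constants are resolved. The default 0.05 ms divides every exposure and
#'   phase offset used by the standard layouts (e.g. 1.25 ms).
#' @param sign +1 for positive-going spikes (default), -1 for negative-going.
#' @return A [fine_grid_trace()] in e-/ms units.
#' @export
spike_train <- function(spike_times, params, baseline_rate, duration,
                        dt = 0.05, sign = 1) {
  stopifnot(inherits(params, "gevi_spike_params"))
  if (dt <= 0 || dt > 0.25) {
    stop("dt must be in (0, 0.25] ms to resolve the fast time constants",
         call. = FALSE)
  }
  if (baseline_rate < 0) stop("baseline_rate must be >= 0", call. = FALSE)
  if (length(spike_times) &&
      (any(spike_times < 0) || any(spike_times >= duration))) {
    stop("spike_times must lie within [0, duration)", call. = FALSE)
  }
  stopifnot(sign %in% c(-1, 1))
  t <- seq(0, duration - dt, by = dt)
  dff <- numeric(length(t))
  for (st in spike_times) dff <- dff + spike_waveform(t - st, params)
  vals <- baseline_rate * (1 + sign * dff)
  vals[vals < 0] <- 0
  fine_grid_trace(vals, dt = dt, t0 = 0, units = "e_per_ms")
}

#' Spatial scene on the fine time grid
#'
#' A 3-D intensity array (rows x cols x fine frames) in e-/ms units, with the
#' shared fine grid step `dt` and an optional named list of logical ROI
#' masks. All pixel traces share the grid.
#'
#' @param intensity 3-D numeric array, values >= 0.
#' @param dt Fine grid step in ms.
#' @param roi Optional named list of logical matrices matching the frame size.
#' @return An object of class `scene_video`.
#' @export
scene_video <- function(intensity, dt, roi = list()) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3, dt > 0,
            all(intensity >= 0))
  for (m in roi) stopifnot(is.logical(m), all(dim(m) == dim(intensity)[1:2]))
  structure(list(intensity = intensity, dt = dt, roi = roi),
            class = "scene_video")
}

#' @export
print.scene_video <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("scene_video: %d x %d pixels, %d fine frames, dt = %g ms\n",
              d[1], d[2], d[3], x$dt))
  if (length(x$roi)) cat("  ROI masks:", paste(names(x$roi), collapse = ", "), "\n")
  invisible(x)
}

#' Scene with a circular soma ROI carrying a shared trace
#'
#' Every pixel inside a disc of radius `radius` around `center` carries the
#' trace `trace_in`; every pixel outside carries the constant `background`
#' rate. The disc mask is attached as ROI `"soma"`.
#'
#' @param trace_in A [fine_grid_trace()] in e-/ms units.
#' @param shape `c(rows, cols)` of the pixel grid.
#' @param center `c(row, col)` of the disc center (1-based, may be fractional).
#' @param radius Disc radius in pixels.
#' @param background Constant background rate in e-/ms.
#' @return A [scene_video()].
#' @export
soma_scene <- function(trace_in, shape, center = (shape + 1) / 2,
                       radius = min(shape) / 4, background = 0) {
  stopifnot(inherits(trace_in, "fine_grid_trace"),
            trace_in$units == "e_per_ms", background >= 0)
  h <- shape[1]; w <- shape[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  l <- length(trace_in$values)
  a <- array(background, dim = c(h, w, l))
  idx <- which(mask)
  for (k in seq_len(l)) {
    frame <- a[, , k]
    frame[idx] <- trace_in$values[k]
    a[, , k] <- frame
  }
  scene_video(a, dt = trace_in$dt, roi = list(soma = mask))
}

#' Scene of a moving ball on a static background
#'
#' A bright disc of radius `radius` moves at constant `velocity` (pixels per
#' ms) from `start`, reflecting off the grid walls (the corresponding
#' velocity component is reversed when the center would leave the valid
#' range). The realized center positions are stored in the `trajectory`
#' attribute, one row per fine frame.
#'
#' @param shape `c(rows, cols)`.
#' @param radius Ball radius in pixels; must be smaller than half the grid.
#' @param start `c(row, col)` initial center.
#' @param velocity `c(d_row, d_col)` in pixels per ms.
#' @param duration Duration in ms.
#' @param dt Fine grid step in ms.
#' @param intensity Ball intensity (e-/ms).
#' @param background Background intensity (e-/ms).
#' @return A [scene_video()] with attribute `trajectory` (frames x 2 matrix).
#' @export
moving_ball_scene <- function(shape, radius, start, velocity, duration,
                              dt = 0.1, intensity = 100, background = 10) {
  h <- shape[1]; w <- shape[2]
  if (2 * radius >= min(h, w)) stop("ball radius too large for grid", call. = FALSE)
  if (any(start < 1 + radius) || start[1] > h - radius || start[2] > w - radius) {
    stop("trajectory start must keep the ball inside the grid", call. = FALSE)
  }
  nf <- floor(duration / dt)
  pos <- matrix(0, nf, 2)
  p <- as.numeric(start)
  v <- as.numeric(velocity)
  lo <- 1 + radius
  hi <- c(h - radius, w - radius)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  a <- array(background, dim = c(h, w, nf))
  for (k in seq_len(nf)) {
    pos[k, ] <- p
    frame <- a[, , k]
    frame[(rr - p[1])^2 + (cc - p[2])^2 <= radius^2] <- intensity
    a[, , k] <- frame
    p <- p + v * dt
    for (j in 1:2) {  # reflect off walls
      if (p[j] < lo) { p[j] <- 2 * lo - p[j]; v[j] <- -v[j] }
      if (p[j] > hi[j]) { p[j] <- 2 * hi[j] - p[j]; v[j] <- -v[j] }
    }
  }
  out <- scene_video(a, dt = dt)
  attr(out, "trajectory") <- pos
  out
}
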