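#' Transfer function of the box exposure
#'
#' Continuous-time Fourier transform of the box exposure `e(t) = 1` on
#' `[0, t_exp]`: `E(f) = t_exp * sinc(pi f t_exp) * exp(-i pi f t_exp)`
#' (with `t_exp` in seconds inside the transform; the returned gain keeps the
#' package's ms convention, so `|E(0)| = t_exp` in ms). The magnitude has
#' exact zeros at `f = n * 1000 / t_exp` Hz, `n != 0`: long exposures act as
#' narrowband notches at multiples of their inverse duration.
#'
#' @param f_hz Frequencies in Hz (vectorized).
#' @param t_exp Exposure duration in ms.
#' @return Complex gain values.
#' @export
exposure_transfer <- function(f_hz, t_exp) {
  stopifnot(t_exp > 0)
  x <- pi * f_hz * (t_exp / 1000)
  s <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  t_exp * s * exp(-1i * x)
}

#' Exact attenuation nulls of a box exposure
#'
#' @param t_exp Exposure duration in ms.
#' @param f_max Upper frequency bound in Hz.
#' @return Sorted positive null frequencies (Hz) up to `f_max`:
#'   `n * 1000 / t_exp`.
#' @export
exposure_nulls <- function(t_exp, f_max = 1000) {
  f1 <- 1000 / t_exp
  if (f1 > f_max) return(numeric(0))
  seq(f1, f_max, by = f1)
}

#' Spectrum of one phase-offset sampled pixel
#'
#' A pixel with exposure `t_exp` sampled at period `t_exp` produces the
#' aliased spectrum
#' \deqn{Y_k(f) = \frac{1}{T_E} \sum_n E\!\left(f - \frac{n}{T_E}\right)
#'       e^{-j 2 \pi n k / K},}
#' where `k` is the pixel's phase index among `K` evenly staggered phases
#' (offset `k * t_exp / K`) and the sum runs over replica indices
#' `|n| <= n_replicas`. Replicas beyond the truncation bound contribute
#' `O(1/(n_replicas * f_s))` since `|E(f)|` decays as `1/f`.
#'
#' @param t_exp Exposure duration and sample period in ms.
#' @param phase_index Phase index `k`, `0 <= k < n_phases`.
#' @param n_phases Number of staggered phases `K` (>= 1).
#' @param f_grid Frequency grid in Hz (default 0 to 1000 Hz, 0.5 Hz step).
#' @param n_replicas Replica truncation (default 16); must cover the grid
#'   span plus a margin.
#' @return An object of class `spectrum_report`: list with `f_hz`, complex
#'   `gain`, `nulls_hz` and `effective_bandwidth_hz`.
#' @export
sampled_spectrum <- function(t_exp, phase_index = 0, n_phases = 1,
                             f_grid = seq(0, 1000, by = 0.5),
                             n_replicas = 16) {
  stopifnot(n_phases >= 1, phase_index >= 0, phase_index < n_phases)
  fs <- 1000 / t_exp  # per-pixel sampling rate, Hz
  if (n_replicas < ceiling(max(abs(f_grid)) / fs) + 2) {
    stop("n_replicas too small for the requested frequency span", call. = FALSE)
  }
  gain <- rep(0 + 0i, length(f_grid))
  for (n in -n_replicas:n_replicas) {
    gain <- gain + exposure_transfer(f_grid - n * fs, t_exp) *
      exp(-2i * pi * n * phase_index / n_phases)
  }
  gain <- gain / t_exp
  structure(list(f_hz = f_grid, gain = gain,
                 nulls_hz = exposure_nulls(t_exp, max(f_grid)),
                 effective_bandwidth_hz = fs / 2),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("spectrum_report: %d frequencies in [%g, %g] Hz, bandwidth %g Hz\n",
              length(x$f_hz), min(x$f_hz), max(x$f_hz), x$effective_bandwidth_hz))
  if (length(x$nulls_hz)) {
    cat("  exposure nulls (Hz):", paste(utils::head(x$nulls_hz, 6), collapse = ", "),
        if (length(x$nulls_hz) > 6) "..." else "", "\n")
  }
  invisible(x)
}

#' Averaged spectrum of K staggered phases
#'
#' The unweighted mean of the `K` phase spectra. The phase factors
#' `1 + e^{-j2\pi n/K} + ... + e^{-j2\pi n (K-1)/K}` cancel every replica
#' whose index is not a multiple of `K`, leaving
#' \deqn{Y_{avg}(f) = \frac{1}{T_E} \sum_n E\!\left(f - \frac{Kn}{T_E}\right):}
#' replicas are spaced `K` times further apart, so the ensemble behaves like
#' a single pixel sampled `K` times faster (with the same exposure), raising
#' the alias-free bandwidth by the factor `K`. A `weights` argument allows
#' unequal per-phase pixel counts (an extension beyond the evenly weighted
#' analysis; the default is the unweighted mean).
#'
#' @inheritParams sampled_spectrum
#' @param weights Optional per-phase weights (length `n_phases`); normalized
#'   to sum to 1.
#' @return A `spectrum_report`; `effective_bandwidth_hz` is
#'   `n_phases / (2 t_exp)` in Hz for the unweighted case.
#' @export
averaged_spectrum <- function(t_exp, n_phases,
                              f_grid = seq(0, 1000, by = 0.5),
                              n_replicas = 16, weights = NULL) {
  stopifnot(n_phases >= 1)
  if (is.null(weights)) {
    weights <- rep(1 / n_phases, n_phases)
  } else {
    stopifnot(length(weights) == n_phases, all(weights >= 0), sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  acc <- rep(0 + 0i, length(f_grid))
  for (k in seq_len(n_phases) - 1L) {
    acc <- acc + weights[k + 1] *
      sampled_spectrum(t_exp, k, n_phases, f_grid, n_replicas)$gain
  }
  structure(list(f_hz = f_grid, gain = acc,
                 nulls_hz = exposure_nulls(t_exp, max(f_grid)),
                 effective_bandwidth_hz = n_phases * 1000 / t_exp / 2),
            class = "spectrum_report")
}

#' Nyquist temporal resolution of a sampling rate
#'
#' The shortest resolvable temporal feature at sampling rate `fs_hz`,
#' defined as `2 / fs`, returned in ms.
#'
#' @param fs_hz Sampling rate in Hz.
#' @return Resolution in ms (`2000 / fs_hz`).
#' @export
nyquist_resolution <- function(fs_hz) {
  stopifnot(all(fs_hz > 0))
  2000 / fs_hz
}

#' Equivalent sampling rate of a pixel ensemble
#'
#' Merges the sample timestamps of all configurations (over their common
#' repetition period) and returns `1000 / min(gap)` Hz. If the merged gaps
#' are not uniform, the reciprocal of the median gap is returned with a
#' warning.
#'
#' @param x An [exposure_map()], a list of [exposure_config()] objects, or a
#'   single config.
#' @return Equivalent rate in Hz.
#' @export
effective_rate <- function(x) {
  configs <- if (inherits(x, "exposure_map")) {
    lapply(map_groups(x), `[[`, "config")
  } else if (inherits(x, "exposure_config")) {
    list(x)
  } else {
    stopifnot(all(vapply(x, inherits, TRUE, "exposure_config")))
    x
  }
  # merged timestamps over a horizon of several common periods
  horizon <- 4 * max(vapply(configs, function(cf) cf$t_sample + cf$delta, 1.0))
  times <- sort(unique(round(unlist(lapply(configs, function(cf) {
    seq(cf$delta, horizon, by = cf$t_sample)
  })), 9)))
  gaps <- diff(times)
  gaps <- gaps[gaps > 1e-9]
  if (length(gaps) == 0) return(period_to_rate(configs[[1]]$t_sample))
  if (max(gaps) - min(gaps) > 1e-6) {
    warning("merged timestamps are not uniform; reporting 1/median(gap)")
    return(period_to_rate(stats::median(gaps)))
  }
  period_to_rate(min(gaps))
}

#' Frequency coverage of a multi-exposure configuration
#'
#' For each frequency, the best (maximum) normalized exposure gain
#' `|E(f)|/t_exp` across the listed exposure durations. A single exposure has
#' hard notches at multiples of its inverse duration; mixing distinct
#' exposures keeps every frequency covered as long as their null sets do not
#' coincide below the merged Nyquist frequency.
#'
#' @param exposures Numeric vector of >= 1 exposure durations (ms).
#' @param f_grid Frequency grid in Hz.
#' @param threshold Normalized-gain threshold below which a frequency counts
#'   as attenuated (default 0.05).
#' @return A data frame with `f_hz` and `max_gain` (normalized), with
#'   attributes `gaps_hz` (frequencies below the merged Nyquist where
#'   `max_gain < threshold`) and `nyquist_hz`.
#' @export
config_frequency_coverage <- function(exposures,
                                      f_grid = seq(0, 1000, by = 0.5),
                                      threshold = 0.05) {
  stopifnot(length(exposures) >= 1, all(exposures > 0))
  gains <- vapply(exposures, function(te) {
    Mod(exposure_transfer(f_grid, te)) / te
  }, numeric(length(f_grid)))
  mg <- apply(matrix(gains, nrow = length(f_grid)), 1, max)
  # merged Nyquist: sum of the individual rates (distinct-speed pixels
  # interleave their samples)
  nyq <- sum(1000 / exposures) / 2
  out <- data.frame(f_hz = f_grid, max_gain = mg)
  gaps <- f_grid[mg < threshold & f_grid > 0]
  attr(out, "gaps_hz") <- gaps
  attr(out, "gaps_below_nyquist_hz") <- gaps[gaps < nyq]
  attr(out, "nyquist_hz") <- nyq
  out
}
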