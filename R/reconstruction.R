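#' Sub-ROI time series: per-group pixel average
#'
#' For each configuration group of a sampled scene, averages the masked
#' pixels' samples at each timestamp, yielding one [sampled_series()] per
#' group (groups with no masked pixel are dropped).
#'
#' @param sampled A `sampled_scene` from [sample_scene()].
#' @param mask Logical matrix matching the pixel grid.
#' @return Named list of [sampled_series()], one per contributing group.
#' @export
subroi_series <- function(sampled, mask) {
  stopifnot(inherits(sampled, "sampled_scene"), is.logical(mask),
            all(dim(mask) == sampled$shape))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  sel <- which(mask)
  out <- list()
  for (g in sampled$groups) {
    rows <- g$pixels %in% sel
    if (!any(rows)) next
    out[[length(out) + 1]] <- sampled_series(
      g$times, colMeans(g$values[rows, , drop = FALSE]), g$config)
  }
  if (!length(out)) stop("mask covers no sampled pixel", call. = FALSE)
  names(out) <- vapply(out, function(s) {
    sprintf("t_exp%g_delta%g", s$config$t_exp, s$config$delta)
  }, "")
  out
}

butter_filtfilt <- function(x, w, type) {
  ba <- signal::butter(4, w, type = type)
  as.numeric(signal::filtfilt(ba, x))
}

#' Band-pass condition a sampled series
#'
#' 4th-order Butterworth band-pass applied forward and backward (zero phase,
#' so peak times are not skewed across groups with different rates): a
#' high-pass at `low_hz` removes drift such as photobleaching, and a low-pass
#' at `high_hz` (default 90 % of the series' Nyquist frequency) removes
#' content too close to the sampling Nyquist.
#'
#' @param series A [sampled_series()] or numeric vector.
#' @param fs_hz Sampling rate in Hz (taken from the series config if absent).
#' @param low_hz High-pass cutoff in Hz (default 0.5).
#' @param high_hz Low-pass cutoff in Hz (default `0.45 * fs_hz`, i.e. 90 % of
#'   Nyquist).
#' @return Same type as the input, filtered.
#' @export
bandpass_condition <- function(series, fs_hz = NULL, low_hz = 0.5,
                               high_hz = NULL) {
  is_series <- inherits(series, "sampled_series")
  x <- if (is_series) series$value else series
  if (is.null(fs_hz)) {
    if (!is_series) stop("fs_hz required for a bare numeric series", call. = FALSE)
    fs_hz <- period_to_rate(series$config$t_sample)
  }
  if (is.null(high_hz)) high_hz <- 0.9 * fs_hz / 2
  if (high_hz <= low_hz || high_hz >= fs_hz / 2) {
    stop("sampling rate too low for the requested pass-band", call. = FALSE)
  }
  y <- butter_filtfilt(x, high_hz / (fs_hz / 2), "low")
  y <- butter_filtfilt(y, low_hz / (fs_hz / 2), "high")
  if (is_series) sampled_series(series$time_ms, y, series$config, series$units)
  else y
}

#' Stacked ridge-interpolation problem
#'
#' Concatenates per-group sampling matrices and measurements onto a shared
#' fine grid of length `l_fine` at step `dt`, defining the regression
#' `y = E v + phi` whose ridge solution estimates the common underlying ROI
#' signal `v`.
#'
#' @param groups List of [sampled_series()] objects (each carries its
#'   [exposure_config()]).
#' @param l_fine Fine-grid length.
#' @param dt Fine-grid step in ms (all configs must be aligned to it).
#' @param lambda Ridge weight; default `100 * mean(diag(E'E))`, deliberately
#'   large so the solution conservatively under-fits noise.
#' @return Object of class `recon_problem`: `e` (stacked matrix), `y`
#'   (stacked values), `lambda`, `l_fine`, `dt`.
#' @export
stack_problem <- function(groups, l_fine, dt, lambda = NULL) {
  stopifnot(length(groups) >= 1)
  mats <- list(); ys <- list()
  for (g in groups) {
    stopifnot(inherits(g, "sampled_series"))
    e <- build_sampling_matrix(g$config, l_fine, dt)
    st <- attr(e, "sample_times_ms")
    keep <- match(round(st, 9), round(g$time_ms, 9))
    if (anyNA(keep)) {
      # series may be shorter than the grid allows; restrict rows
      ok <- !is.na(keep)
      if (!any(ok)) stop("series does not overlap the target window", call. = FALSE)
      e <- e[ok, , drop = FALSE]
      keep <- keep[ok]
    }
    mats[[length(mats) + 1]] <- e
    ys[[length(ys) + 1]] <- g$value[keep]
  }
  e <- do.call(rbind, mats)
  y <- unlist(ys)
  if (is.null(lambda)) lambda <- 100 * mean(colSums(e^2))
  structure(list(e = e, y = y, lambda = lambda, l_fine = l_fine, dt = dt),
            class = "recon_problem")
}

#' Closed-form ridge solution of a stacked problem
#'
#' Solves `v_hat = (E'E + lambda I)^{-1} E' y`. With `lambda = 0` the normal
#' equations must be full rank, otherwise an error instructs choosing
#' `lambda > 0`. For very large `lambda` the solution tends to a scaled
#' `E' y`, which is up-sampling plus interpolation of the pixel outputs.
#'
#' @param problem A `recon_problem` from [stack_problem()].
#' @return A data frame of class `roi_series` with `time_ms` (fine-grid bin
#'   starts) and `value`, and attribute `lambda`.
#' @export
ridge_solve <- function(problem) {
  stopifnot(inherits(problem, "recon_problem"), problem$lambda >= 0)
  g <- crossprod(problem$e)
  diag(g) <- diag(g) + problem$lambda
  rhs <- crossprod(problem$e, problem$y)
  v <- tryCatch(solve(g, rhs), error = function(err) {
    if (problem$lambda == 0) {
      stop("normal equations are singular at lambda = 0; set lambda > 0",
           call. = FALSE)
    }
    stop(err)
  })
  out <- data.frame(time_ms = (seq_len(problem$l_fine) - 1) * problem$dt,
                    value = as.numeric(v))
  attr(out, "lambda") <- problem$lambda
  class(out) <- c("roi_series", "data.frame")
  out
}

merge_groups <- function(groups, rate_units = TRUE, recenter = FALSE) {
  tabs <- lapply(groups, function(g) {
    v <- if (rate_units) g$value / g$config$t_exp else g$value
    t <- g$time_ms - if (recenter) g$config$t_exp / 2 else 0
    data.frame(time_ms = t, value = v)
  })
  tab <- do.call(rbind, tabs)
  tab <- tab[order(tab$time_ms), ]
  # average exact-duplicate timestamps
  key <- round(tab$time_ms, 9)
  if (anyDuplicated(key)) {
    tab <- stats::aggregate(value ~ time_ms,
                            data = data.frame(time_ms = key, value = tab$value),
                            FUN = mean)
  }
  tab
}

#' Merge staggered groups and interpolate to a uniform high-rate grid
#'
#' The practical reconstruction path (the large-ridge-weight limit of
#' [ridge_solve()]): samples of all groups are normalized to rate units
#' (electrons divided by each group's exposure), merged by timestamp, and
#' linearly interpolated onto a uniform grid at `target_rate_hz`. Timestamps
#' use the end-of-exposure convention by default; `recenter = TRUE` shifts
#' each group to its window midpoint instead.
#'
#' @param groups List of [sampled_series()] objects.
#' @param target_rate_hz Target uniform rate; must not exceed the merged
#'   equivalent rate.
#' @param recenter Re-center timestamps to exposure-window midpoints.
#' @return A data frame of class `roi_series` with `time_ms` and `value`
#'   (e-/ms rate units), and attributes `rate_hz` and `path = "interp"`.
#' @export
upsample_interpolate <- function(groups, target_rate_hz, recenter = FALSE) {
  stopifnot(length(groups) >= 1)
  eff <- effective_rate(lapply(groups, `[[`, "config"))
  if (target_rate_hz > eff + 1e-9) {
    stop(sprintf("target rate %g Hz exceeds the merged equivalent rate %g Hz",
                 target_rate_hz, eff), call. = FALSE)
  }
  tab <- merge_groups(groups, rate_units = TRUE, recenter = recenter)
  step <- rate_to_period(target_rate_hz)
  grid <- seq(tab$time_ms[1], tab$time_ms[nrow(tab)], by = step)
  out <- data.frame(time_ms = grid,
                    value = stats::approx(tab$time_ms, tab$value,
                                          xout = grid)$y)
  attr(out, "rate_hz") <- target_rate_hz
  attr(out, "path") <- "interp"
  class(out) <- c("roi_series", "data.frame")
  out
}

#' Fuse pixel groups of different speeds into one high-rate series
#'
#' Each group is band-pass conditioned at its own bandwidth (high-pass
#' `low_hz`, low-pass at 90 % of its own Nyquist frequency), normalized to
#' rate units, merged by timestamp and linearly interpolated onto the target
#' grid. With all exposures identical this reduces to
#' [upsample_interpolate()] applied to conditioned series.
#'
#' @param groups List of [sampled_series()] with >= 1 distinct exposures.
#' @param target_rate_hz Target uniform rate in Hz.
#' @param low_hz Common high-pass cutoff (default 0.5 Hz).
#' @param recenter Re-center timestamps to exposure midpoints.
#' @return A `roi_series` data frame (see [upsample_interpolate()]).
#' @export
multispeed_fuse <- function(groups, target_rate_hz, low_hz = 0.5,
                            recenter = FALSE) {
  conditioned <- lapply(groups, function(g) {
    bandpass_condition(g, low_hz = low_hz)
  })
  out <- upsample_interpolate(conditioned, target_rate_hz, recenter = recenter)
  attr(out, "path") <- "multispeed"
  out
}

#' @export
print.roi_series <- function(x, ...) {
  r <- attr(x, "rate_hz")
  cat(sprintf("roi_series: %d points%s%s\n", nrow(x),
              if (!is.null(r)) sprintf(" at %g Hz", r) else "",
              if (!is.null(attr(x, "path"))) paste0(", path = ", attr(x, "path")) else ""))
  invisible(as.data.frame(x))
}
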