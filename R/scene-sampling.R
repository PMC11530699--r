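#' Sample a scene with a per-pixel exposure map
#'
#' Applies each pixel's exposure configuration to its fine-grid trace,
#' producing one group of sampled pixels per distinct configuration. Noise is
#' drawn per pixel and per sample; results are reproducible under `seed`.
#'
#' @param scene A [scene_video()].
#' @param map An [exposure_map()] matching the scene's pixel grid.
#' @param noise A [noise_params()] or `NULL`.
#' @param seed Optional integer seed.
#' @return An object of class `sampled_scene`: a list of groups, each with
#'   `config`, `pixels` (linear indices), `times` (ms) and `values`
#'   (pixels x samples matrix of electrons), plus the grid `shape` and the
#'   scene `dt`.
#' @export
sample_scene <- function(scene, map, noise = NULL, seed = NULL) {
  stopifnot(inherits(scene, "scene_video"), inherits(map, "exposure_map"))
  d <- dim(scene$intensity)
  if (!all(dim(map) == d[1:2])) stop("map shape does not match scene", call. = FALSE)
  groups <- map_groups(map)
  flat <- matrix(scene$intensity, d[1] * d[2], d[3])
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(groups, function(g) {
    check_on_grid(g$config, scene$dt)
    k <- round(g$config$t_exp / scene$dt)
    total <- d[3] * scene$dt
    m_min <- max(1L, as.integer(ceiling((g$config$t_exp - g$config$delta) /
                                          g$config$t_sample - 1e-9)))
    m_max <- as.integer(floor((total - g$config$delta) / g$config$t_sample + 1e-9))
    ms <- m_min:m_max
    ends <- round((g$config$delta + ms * g$config$t_sample) / scene$dt)
    cs <- cbind(0, t(apply(flat[g$pixels, , drop = FALSE], 1, cumsum))) * scene$dt
    vals <- cs[, ends + 1, drop = FALSE] - cs[, ends - k + 1, drop = FALSE]
    noisy <- matrix(draw_noise(as.numeric(vals), noise, g$config$t_exp),
                    nrow = nrow(vals))
    list(config = g$config, pixels = g$pixels,
         times = g$config$delta + ms * g$config$t_sample, values = noisy)
  })
  structure(list(groups = out, shape = d[1:2], dt = scene$dt),
            class = "sampled_scene")
}

#' @export
print.sampled_scene <- function(x, ...) {
  cat(sprintf("sampled_scene: %d x %d pixels, %d config group(s)\n",
              x$shape[1], x$shape[2], length(x$groups)))
  for (g in x$groups) {
    cat(sprintf("  t_exp = %g ms, delta = %g ms: %d pixels, %d samples\n",
                g$config$t_exp, g$config$delta, length(g$pixels), length(g$times)))
  }
  invisible(x)
}

#' Assemble a full-resolution frame stream from sampled pixels
#'
#' At each readout tick (every `frame_period` ms) the stream shows, at every
#' pixel location, that pixel's most recent completed sample. Staggered
#' exposure thereby embeds motion within full-resolution frames.
#'
#' @param sampled A `sampled_scene` from [sample_scene()].
#' @param frame_period Tick period in ms (default: smallest gap between
#'   distinct sample times across groups).
#' @return A list with `frames` (rows x cols x n_ticks array) and
#'   `times` (tick times in ms).
#' @export
assemble_frames <- function(sampled, frame_period = NULL) {
  stopifnot(inherits(sampled, "sampled_scene"))
  all_t <- sort(unique(unlist(lapply(sampled$groups, `[[`, "times"))))
  if (is.null(frame_period)) frame_period <- min(diff(all_t))
  t0 <- min(all_t)
  ticks <- seq(t0, max(all_t), by = frame_period)
  h <- sampled$shape[1]; w <- sampled$shape[2]
  frames <- array(NA_real_, dim = c(h, w, length(ticks)))
  for (g in sampled$groups) {
    # index of latest completed sample at each tick
    last <- findInterval(ticks + 1e-9, g$times)
    for (j in seq_along(ticks)) {
      if (last[j] >= 1) {
        f <- frames[, , j]
        f[g$pixels] <- g$values[, last[j]]
        frames[, , j] <- f
      }
    }
  }
  list(frames = frames, times = ticks)
}

#' Split a tiled acquisition into per-group sub-frame videos
#'
#' For a 2x2-tiled layout (staggered 4-phase or multi-speed), extracts one
#' quarter-resolution video per configuration group, each at that group's own
#' frame rate `1000 / t_sample` Hz. For staggered layouts the groups
#' interleave into a stream whose period is `t_sample / n_groups`.
#'
#' @param sampled A `sampled_scene` whose map used a 2x2-tiled (or uniform)
#'   layout.
#' @return A list of per-group videos, each with `config`, `times` (ms),
#'   `frames` (rows/2 x cols/2 x samples array for tiled layouts) and
#'   `rate_hz`.
#' @export
split_subframes <- function(sampled) {
  stopifnot(inherits(sampled, "sampled_scene"))
  h <- sampled$shape[1]; w <- sampled$shape[2]
  lapply(sampled$groups, function(g) {
    rows <- (g$pixels - 1) %% h + 1
    cols <- (g$pixels - 1) %/% h + 1
    ur <- sort(unique(rows)); uc <- sort(unique(cols))
    if (length(ur) * length(uc) != length(g$pixels)) {
      stop("group pixels do not form a separable sub-grid; split_subframes needs a tiled or uniform layout",
           call. = FALSE)
    }
    ord <- order(cols, rows)
    v <- array(g$values[ord, , drop = FALSE],
               dim = c(length(ur), length(uc), length(g$times)))
    list(config = g$config, times = g$times, frames = v,
         rate_hz = period_to_rate(g$config$t_sample))
  })
}

#' Interleave sub-frame videos into a single stream
#'
#' Merges the per-group videos of [split_subframes()] by timestamp. The
#' equivalent rate of the merged stream is `1000 / min(gap)` Hz where `gap`
#' runs over the merged inter-sample intervals.
#'
#' @param subframes Output of [split_subframes()].
#' @return A list with `times` (sorted ms), `group` (index of the source
#'   group per frame), `frame_index` (sample index within its group) and
#'   `rate_hz` (equivalent rate of the merged stream).
#' @export
interleave_subframes <- function(subframes) {
  tab <- do.call(rbind, lapply(seq_along(subframes), function(i) {
    data.frame(time_ms = subframes[[i]]$times, group = i,
               frame_index = seq_along(subframes[[i]]$times))
  }))
  tab <- tab[order(tab$time_ms), ]
  gaps <- diff(tab$time_ms)
  gaps <- gaps[gaps > 1e-9]
  list(times = tab$time_ms, group = tab$group, frame_index = tab$frame_index,
       rate_hz = if (length(gaps)) period_to_rate(min(gaps)) else NA_real_)
}

#' Box-average and decimate a sampled series
#'
#' Moving average over `factor` consecutive samples (DC gain 1), keeping
#' every `factor`-th sample; the output timestamp of each kept sample is the
#' time of the last contributing input sample (end-of-window convention).
#' Used to mimic a slower camera from a faster series, e.g. a 200 Hz stream
#' from an 800 Hz acquisition with `factor = 4`.
#'
#' @param series A [sampled_series()].
#' @param factor Integer >= 1.
#' @return A [sampled_series()] at `factor` times the input sample period.
#' @export
box_downsample <- function(series, factor) {
  stopifnot(inherits(series, "sampled_series"), factor >= 1,
            factor == round(factor))
  n <- length(series$value)
  if (n < factor) stop("series shorter than downsampling factor", call. = FALSE)
  if (factor == 1) return(series)
  keep <- seq(factor, n, by = factor)
  cs <- c(0, cumsum(series$value))
  avg <- (cs[keep + 1] - cs[keep + 1 - factor]) / factor
  cfg <- exposure_config(series$config$t_exp,
                         series$config$delta %% (series$config$t_sample * factor),
                         series$config$t_sample * factor)
  sampled_series(series$time_ms[keep], avg, cfg, units = series$units)
}
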