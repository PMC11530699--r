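#' Write / read a fine-grid trace as CSV
#'
#' Two columns (`time_ms`, `value`) preceded by a one-line unit header of the
#' form `# units: e_per_ms`.
#'
#' @param trace A [fine_grid_trace()].
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a [fine_grid_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fine_grid_trace"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", trace$units), con)
  utils::write.csv(data.frame(time_ms = sprintf("%.15g", trace_times(trace)),
                              value = sprintf("%.15g", trace$values)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  units <- sub("^# units: *", "", hdr)
  tab <- utils::read.csv(path, comment.char = "#")
  dt <- round(stats::median(diff(tab$time_ms)), 9)  # snap to the ns grid
  fine_grid_trace(tab$value, dt = dt, t0 = tab$time_ms[1], units = units)
}

#' Write / read a sampled series as CSV
#'
#' Columns `time_ms`, `value` preceded by `#`-prefixed provenance headers
#' recording the exposure configuration and units.
#'
#' @param series A [sampled_series()].
#' @param path File path.
#' @return The path (write) or a [sampled_series()] (read).
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "sampled_series"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# t_exp_ms: %.15g", series$config$t_exp),
               sprintf("# delta_ms: %.15g", series$config$delta),
               sprintf("# t_sample_ms: %.15g", series$config$t_sample),
               sprintf("# units: %s", series$units)), con)
  utils::write.csv(data.frame(time_ms = sprintf("%.15g", series$time_ms),
                              value = sprintf("%.15g", series$value)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  hdr <- readLines(path, n = 4)
  val <- function(key) sub(sprintf("^# %s: *", key), "", grep(key, hdr, value = TRUE))
  cfg <- exposure_config(as.numeric(val("t_exp_ms")),
                         as.numeric(val("delta_ms")),
                         as.numeric(val("t_sample_ms")))
  tab <- utils::read.csv(path, comment.char = "#")
  sampled_series(tab$time_ms, tab$value, cfg, units = val("units"))
}

#' Write / read a reconstructed ROI series as CSV
#'
#' Columns `time_ms`, `value` with `#`-prefixed provenance headers (rate and
#' reconstruction path).
#'
#' @param roi A `roi_series` data frame.
#' @param path File path.
#' @return The path (write) or a `roi_series` (read).
#' @export
write_roi_csv <- function(roi, path) {
  stopifnot(inherits(roi, "roi_series"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz: %.15g",
                       if (is.null(attr(roi, "rate_hz"))) NA else attr(roi, "rate_hz")),
               sprintf("# path: %s",
                       if (is.null(attr(roi, "path"))) "ridge" else attr(roi, "path"))),
             con)
  utils::write.csv(data.frame(time_ms = sprintf("%.15g", roi$time_ms),
                              value = sprintf("%.15g", roi$value)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  tab <- utils::read.csv(path, comment.char = "#")
  out <- data.frame(time_ms = tab$time_ms, value = tab$value)
  attr(out, "rate_hz") <- as.numeric(sub("^# rate_hz: *", "", hdr[1]))
  attr(out, "path") <- sub("^# path: *", "", hdr[2])
  class(out) <- c("roi_series", "data.frame")
  out
}

#' Export / import a scene as a multi-page 16-bit TIFF
#'
#' One page per fine-grid frame, 16-bit unsigned, values clipped to
#' `[0, 65535]` and rounded to integers. The fine grid step is not stored in
#' the TIFF; pass it back to the reader.
#'
#' @param scene A [scene_video()].
#' @param path File path.
#' @param dt Fine grid step in ms for the reader.
#' @return The path (write) or a [scene_video()] (read).
#' @export
write_scene_tiff <- function(scene, path) {
  stopifnot(inherits(scene, "scene_video"))
  d <- dim(scene$intensity)
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- round(scene$intensity[, , k])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_scene_tiff
#' @export
read_scene_tiff <- function(path, dt) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) a[, , k] <- round(pages[[k]] * 65535)
  scene_video(a, dt = dt)
}

#' Write a sampled scene as per-group TIFF stacks with timestamp sidecars
#'
#' For each configuration group, writes `<stem>_group<k>.tif` (pixels of the
#' group reshaped to their sub-grid when tiled, one page per sample, 16-bit
#' after rounding) and `<stem>_group<k>_times.csv` (sample timestamps and the
#' group's exposure configuration as header comments).
#'
#' @param sampled A `sampled_scene`.
#' @param stem Path stem (no extension).
#' @return Character vector of written paths, invisibly.
#' @export
write_sampled_video <- function(sampled, stem) {
  stopifnot(inherits(sampled, "sampled_scene"))
  paths <- character(0)
  sub <- split_subframes(sampled)
  for (k in seq_along(sub)) {
    g <- sub[[k]]
    tp <- sprintf("%s_group%d.tif", stem, k)
    pages <- lapply(seq_along(g$times), function(j) {
      m <- round(g$frames[, , j, drop = TRUE])
      m[m < 0] <- 0; m[m > 65535] <- 65535
      matrix(m / 65535, dim(g$frames)[1], dim(g$frames)[2])
    })
    tiff::writeTIFF(pages, tp, bits.per.sample = 16, compression = "none")
    cp <- sprintf("%s_group%d_times.csv", stem, k)
    con <- file(cp, "wb")
    writeLines(c(sprintf("# t_exp_ms: %.15g", g$config$t_exp),
                 sprintf("# delta_ms: %.15g", g$config$delta),
                 sprintf("# t_sample_ms: %.15g", g$config$t_sample)), con)
    utils::write.csv(data.frame(page = seq_along(g$times),
                                time_ms = sprintf("%.15g", g$times)),
                     con, row.names = FALSE, quote = FALSE)
    close(con)
    paths <- c(paths, tp, cp)
  }
  invisible(paths)
}

#' Write / read an ROI mask as plain text
#'
#' One row of space-separated 0/1 per pixel row.
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return The path (write) or a logical matrix (read).
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(is.logical(mask))
  writeLines(apply(mask * 1L, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  rows <- strsplit(readLines(path), " ")
  matrix(as.integer(unlist(rows)) == 1L, nrow = length(rows), byrow = TRUE)
}

#' Write an events table as CSV
#'
#' @param events Data frame from [detect_spikes()] or [match_events()].
#' @param path File path.
#' @param series_id Identifier recorded in a `series_id` column.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, series_id = "roi") {
  events$series_id <- series_id
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.csv(events, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
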