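#' Array-level exposure map
#'
#' Per-pixel exposure configurations for a pixel grid, stored as three
#' numeric matrices (`t_exp`, `delta`, `t_sample`, all in ms) plus a layout
#' tag: `"uniform"`, `"staggered"`, `"tiled"`, `"multispeed"`, `"random"` or
#' `"custom"`. Pixels are addressed `[row, col]`, 1-based, with 2x2 tiles
#' anchored at `[1, 1]`.
#'
#' @param t_exp,delta,t_sample Numeric matrices of equal shape (ms).
#' @param layout Layout tag.
#' @return An object of class `exposure_map`.
#' @export
exposure_map <- function(t_exp, delta, t_sample = t_exp, layout = "custom") {
  stopifnot(is.matrix(t_exp), all(dim(delta) == dim(t_exp)),
            all(dim(t_sample) == dim(t_exp)))
  if (any(t_exp <= 0) || any(t_exp > t_sample) ||
      any(delta < 0) || any(delta >= t_sample)) {
    stop("invalid pixel config: need 0 < t_exp <= t_sample and 0 <= delta < t_sample",
         call. = FALSE)
  }
  structure(list(t_exp = t_exp, delta = delta, t_sample = t_sample,
                 layout = layout),
            class = "exposure_map")
}

#' @export
print.exposure_map <- function(x, ...) {
  cat(sprintf("exposure_map: %d x %d pixels, layout = %s, %d distinct configs\n",
              nrow(x$t_exp), ncol(x$t_exp), x$layout, length(map_groups(x))))
  invisible(x)
}

#' @export
dim.exposure_map <- function(x) dim(x$t_exp)

#' Group map pixels by shared configuration
#'
#' @param map An [exposure_map()].
#' @return A list with one element per distinct configuration, each holding
#'   `config` (an [exposure_config()]) and `pixels` (linear column-major
#'   indices into the grid).
#' @export
map_groups <- function(map) {
  stopifnot(inherits(map, "exposure_map"))
  key <- paste(map$t_exp, map$delta, map$t_sample, sep = "|")
  idx <- split(seq_along(key), key)
  # stable order: by first occurrence
  idx <- idx[order(vapply(idx, min, 1L))]
  lapply(idx, function(i) {
    list(config = exposure_config(map$t_exp[i[1]], map$delta[i[1]],
                                  map$t_sample[i[1]]),
         pixels = i)
  })
}

#' Staggered phase-offset exposure map
#'
#' All pixels share the exposure duration `t_exp` (= sample period), with
#' `n_phases` phase offsets `delta_k = base_offset + k * t_exp / n_phases`,
#' `k = 0 .. n_phases-1`. For `n_phases = 4` the offsets tile in 2x2 blocks
#' (row-major within the block) so that every 2x2-aligned region contains all
#' four phases; `n_phases = 1` yields a uniform (conventional-sensor) map;
#' other counts fall back to cyclic assignment along rows.
#'
#' @param shape `c(rows, cols)`.
#' @param t_exp Exposure duration in ms.
#' @param n_phases Number of phases; must divide the exposure evenly on the
#'   fine grid in downstream use.
#' @param base_offset Common offset added to every phase (ms).
#' @return An [exposure_map()] with layout `"staggered"` (or `"uniform"`).
#' @export
make_staggered_map <- function(shape, t_exp, n_phases = 4, base_offset = 0) {
  stopifnot(length(shape) == 2, n_phases >= 1, t_exp > 0)
  h <- shape[1]; w <- shape[2]
  step <- t_exp / n_phases
  if (n_phases == 1) {
    k <- matrix(0L, h, w)
  } else if (n_phases == 4) {
    rr <- matrix(seq_len(h) - 1L, h, w)
    cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
    k <- (rr %% 2L) * 2L + (cc %% 2L)
  } else {
    cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
    rr <- matrix(seq_len(h) - 1L, h, w)
    k <- (cc + rr) %% n_phases
  }
  exposure_map(matrix(t_exp, h, w), (base_offset + k * step) %% t_exp,
               layout = if (n_phases == 1) "uniform" else "staggered")
}

#' Multi-speed exposure map (2x2 tiling)
#'
#' Four exposure durations arranged so that every 2x2 window contains all of
#' them; each pixel samples back-to-back at its own exposure (`t_sample =
#' t_exp`, zero offset), so per-pixel rates are `1000 / t_exp` Hz.
#'
#' @param shape `c(rows, cols)`.
#' @param exposures Numeric vector of exactly 4 exposure durations (ms),
#'   assigned row-major within each 2x2 tile.
#' @return An [exposure_map()] with layout `"multispeed"` (or `"uniform"` if
#'   all four exposures are equal).
#' @export
make_multispeed_map <- function(shape, exposures) {
  stopifnot(length(shape) == 2, length(exposures) == 4, all(exposures > 0))
  h <- shape[1]; w <- shape[2]
  rr <- matrix(seq_len(h) - 1L, h, w)
  cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  k <- (rr %% 2L) * 2L + (cc %% 2L) + 1L
  te <- matrix(exposures[k], h, w)
  exposure_map(te, matrix(0, h, w),
               layout = if (length(unique(exposures)) == 1) "uniform" else "multispeed")
}

#' Randomly permuted exposure map
#'
#' Takes the configurations of an existing map and redistributes them over
#' the grid by a seeded permutation, preserving the multiset of
#' configurations (useful for incoherent sampling layouts).
#'
#' @param map An [exposure_map()].
#' @param seed Integer seed for the permutation.
#' @return An [exposure_map()] with layout `"random"`.
#' @export
make_random_map <- function(map, seed = 1) {
  stopifnot(inherits(map, "exposure_map"))
  set.seed(seed)
  p <- sample(length(map$t_exp))
  d <- dim(map$t_exp)
  exposure_map(matrix(map$t_exp[p], d[1], d[2]),
               matrix(map$delta[p], d[1], d[2]),
               matrix(map$t_sample[p], d[1], d[2]),
               layout = "random")
}

#' Write / read an exposure map as a YAML file
#'
#' The file stores the layout tag and the three per-pixel grids
#' (`t_exp_ms`, `delta_ms`, `t_sample_ms`) row by row. Reading a written
#' file and writing it again reproduces the file byte for byte.
#'
#' @param map An [exposure_map()].
#' @param path File path.
#' @return `write_exposure_map()` returns `path` invisibly;
#'   `read_exposure_map()` returns an [exposure_map()].
#' @export
write_exposure_map <- function(map, path) {
  stopifnot(inherits(map, "exposure_map"))
  obj <- list(
    layout = map$layout,
    shape = as.integer(dim(map$t_exp)),
    t_exp_ms = lapply(seq_len(nrow(map$t_exp)), function(i) as.numeric(map$t_exp[i, ])),
    delta_ms = lapply(seq_len(nrow(map$delta)), function(i) as.numeric(map$delta[i, ])),
    t_sample_ms = lapply(seq_len(nrow(map$t_sample)), function(i) as.numeric(map$t_sample[i, ]))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_exposure_map
#' @export
read_exposure_map <- function(path) {
  obj <- yaml::read_yaml(path)
  h <- obj$shape[1]; w <- obj$shape[2]
  tomat <- function(rows) matrix(unlist(rows), h, w, byrow = TRUE)
  exposure_map(tomat(obj$t_exp_ms), tomat(obj$delta_ms), tomat(obj$t_sample_ms),
               layout = obj$layout)
}
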