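#' Run configuration for an end-to-end scenario
#'
#' Bundles the scene, exposure-map, noise, reconstruction and detection
#' specifications plus the mandatory seed. Round-trips through YAML.
#'
#' @param scene List: `shape`, `duration_ms`, `dt_ms`, `baseline_rate`,
#'   `spike_times_ms`, `preset`, `peak_dff`.
#' @param map List: `kind` (`"staggered"`, `"multispeed"` or `"uniform"`),
#'   plus `t_exp_ms`/`n_phases` or `exposures_ms`.
#' @param noise List: `baseline_rate`, `read_rms_e`, `read_ref_ms`, `shot`,
#'   `read` (or `NULL` for noiseless).
#' @param reconstruct List: `target_rate_hz`, `path` (`"interp"` or
#'   `"ridge"`), optional `lambda`, `low_hz`.
#' @param detect List: `threshold`, `burn_in_ms`.
#' @param seed Integer seed (mandatory).
#' @return A list of class `run_config`.
#' @export
run_config <- function(scene, map, noise, reconstruct, detect, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(scene = scene, map = map, noise = noise,
                 reconstruct = reconstruct, detect = detect,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(x, path) {
  stopifnot(inherits(x, "run_config"))
  yaml::write_yaml(unclass(x), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  run_config(obj$scene, obj$map, obj$noise, obj$reconstruct, obj$detect,
             obj$seed)
}

#' Bundled scenario configurations
#'
#' `scenario_benchtop()` mirrors a bench test of temporal super-resolution:
#' a fast spike train (4 ms half-width, 8 ms inter-spike interval) sampled by
#' four pixel groups at 250 Hz with 1 ms phase steps, noiseless, interpolated
#' to 1000 Hz. `scenario_staggered_culture()` is the dim-culture comparison
#' used throughout the package tests: 10 s of spiking at 10 % dF/F on a
#' 1 e-/ms baseline, 4-phase staggered 5 ms exposure versus uniform 1.25 ms.
#'
#' @param seed Integer seed.
#' @return A [run_config()].
#' @export
scenario_benchtop <- function(seed = 1) {
  run_config(
    scene = list(shape = c(4, 4), duration_ms = 400, dt_ms = 0.1,
                 baseline_rate = 100, peak_dff = 0.1, preset = "benchtop",
                 spike_times_ms = c(120, 128, 136)),
    map = list(kind = "staggered", t_exp_ms = 4, n_phases = 4,
               phase_step_ms = 1),
    noise = NULL,
    reconstruct = list(target_rate_hz = 1000, path = "interp"),
    detect = list(threshold = 5, burn_in_ms = 50, noise_sd = 1),
    seed = seed
  )
}

#' @rdname scenario_benchtop
#' @export
scenario_staggered_culture <- function(seed = 1) {
  run_config(
    scene = list(shape = c(100, 100), duration_ms = 10000, dt_ms = 0.05,
                 baseline_rate = 1, peak_dff = 0.1, preset = "asap3",
                 spike_times_ms = seq(500, 9500, length.out = 20)),
    map = list(kind = "staggered", t_exp_ms = 5, n_phases = 4,
               phase_step_ms = 1.25),
    noise = list(baseline_rate = 1, read_rms_e = 2.6, read_ref_ms = 0.9,
                 shot = TRUE, read = TRUE),
    reconstruct = list(target_rate_hz = 800, path = "interp"),
    detect = list(threshold = 5, burn_in_ms = 400),
    seed = seed
  )
}

scenario_params <- function(cfg) {
  if (identical(cfg$scene$preset, "benchtop")) {
    # 4 ms half-width spike: the asap3-like shape with all time constants
    # scaled by the ratio of target to native half-width
    base <- gevi_preset("asap3", peak_dff = cfg$scene$peak_dff)
    s <- 4 / half_width(base)
    gevi_spike_params(base$tau_rf * s, base$tau_rs * s,
                      base$tau_ff * s, base$tau_fs * s,
                      base$a_r, base$b_r, base$a_f, base$b_f,
                      peak_dff = cfg$scene$peak_dff)
  } else {
    gevi_preset(cfg$scene$preset, peak_dff = cfg$scene$peak_dff)
  }
}

#' Execute an end-to-end scenario
#'
#' Runs simulate -> sample -> reconstruct -> detect and (optionally) writes
#' every intermediate artifact plus a structured log. All randomness derives
#' from `config$seed`; identical configurations produce identical bundles.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `trace`, `groups` (per-group [sampled_series()]),
#'   `roi` (reconstructed `roi_series`), `noise_sd`, `events`, and `log`
#'   (character vector of stage records).
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  logline <- function(stage, ...) {
    sprintf("stage=%s seed=%d %s", stage, config$seed,
            paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                  collapse = " "))
  }
  lg <- character(0)
  params <- scenario_params(config)
  trace <- spike_train(config$scene$spike_times_ms, params,
                       baseline_rate = config$scene$baseline_rate,
                       duration = config$scene$duration_ms,
                       dt = config$scene$dt_ms)
  lg <- c(lg, logline("simulate", n_spikes = length(config$scene$spike_times_ms),
                      duration_ms = config$scene$duration_ms))

  noise <- if (is.null(config$noise)) NULL else {
    noise_params(config$noise$baseline_rate,
                 calibrate_read_noise(config$noise$read_rms_e,
                                      config$noise$read_ref_ms),
                 shot = config$noise$shot, read = config$noise$read)
  }
  m <- config$map
  npx <- prod(config$scene$shape)
  configs <- if (identical(m$kind, "staggered")) {
    lapply(seq_len(m$n_phases) - 1L, function(k) {
      exposure_config(m$t_exp_ms, k * m$phase_step_ms, m$t_exp_ms)
    })
  } else if (identical(m$kind, "multispeed")) {
    lapply(m$exposures_ms, function(te) exposure_config(te))
  } else {
    list(exposure_config(m$t_exp_ms))
  }
  n_per <- max(1L, npx %/% length(configs))
  groups <- lapply(seq_along(configs), function(i) {
    sample_roi_series(trace, configs[[i]], noise, n_pixels = n_per,
                      seed = config$seed * 1000L + i)
  })
  lg <- c(lg, logline("sample", groups = length(groups), pixels_per_group = n_per))

  conditioned <- if (is.null(noise)) {
    groups
  } else {
    lapply(groups, bandpass_condition)
  }
  roi <- if (identical(config$reconstruct$path, "ridge")) {
    prob <- stack_problem(conditioned, length(trace$values), trace$dt,
                          lambda = config$reconstruct$lambda)
    ridge_solve(prob)
  } else {
    upsample_interpolate(conditioned, config$reconstruct$target_rate_hz)
  }
  lg <- c(lg, logline("reconstruct", path = config$reconstruct$path,
                      rate_hz = config$reconstruct$target_rate_hz))

  noise_sd <- if (!is.null(config$detect$noise_sd)) {
    config$detect$noise_sd  # fixed unit (e.g. noiseless bench scenarios)
  } else {
    estimate_noise(roi)
  }
  events <- detect_spikes(roi, noise_sd,
                          threshold = config$detect$threshold,
                          burn_in_ms = config$detect$burn_in_ms)
  lg <- c(lg, logline("detect", noise_sd = sprintf("%.6g", noise_sd),
                      n_events = nrow(events)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace_csv(trace, file.path(out_dir, "trace.csv"))
    for (i in seq_along(groups)) {
      write_series_csv(groups[[i]], file.path(out_dir, sprintf("group%d.csv", i)))
    }
    write_roi_csv(roi, file.path(out_dir, "roi.csv"))
    write_events_csv(events, file.path(out_dir, "events.csv"))
    writeLines(lg, file.path(out_dir, "run.log"))
  }
  list(trace = trace, groups = groups, roi = roi, noise_sd = noise_sd,
       events = events, log = lg)
}

#' Write the canonical small fixtures used by the test suite
#'
#' Generates a single-spike trace, an 8 ms inter-spike-interval train, a
#' static soma scene, a moving-ball scene, a 4-phase staggered map and a
#' multi-speed map, all through the public writers. Everything is
#' regenerated from code; total size is well under 1 MB.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Character vector of written paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- gevi_preset("asap3")
  paths <- character(0)
  add <- function(x) paths <<- c(paths, x)

  add(write_trace_csv(spike_train(50, p, baseline_rate = 20, duration = 150),
                      file.path(dir, "single_spike.csv")))
  add(write_trace_csv(spike_train(c(60, 68, 76), p, baseline_rate = 20,
                                  duration = 200),
                      file.path(dir, "train_8ms_isi.csv")))
  static <- soma_scene(spike_train(numeric(0), p, 50, duration = 20),
                       shape = c(8, 8), radius = 2.5)
  add(write_scene_tiff(static, file.path(dir, "static_scene.tif")))
  ball <- moving_ball_scene(c(16, 16), radius = 2, start = c(5, 5),
                            velocity = c(0.05, 0.08), duration = 40, dt = 1)
  add(write_scene_tiff(ball, file.path(dir, "moving_ball.tif")))
  add(write_exposure_map(make_staggered_map(c(8, 8), t_exp = 5, n_phases = 4),
                         file.path(dir, "map_staggered.yaml")))
  add(write_exposure_map(make_multispeed_map(c(8, 8), c(1.9, 3.8, 7.7, 15.4)),
                         file.path(dir, "map_multispeed.yaml")))
  add(write_exposure_map(
    make_random_map(make_staggered_map(c(8, 8), 5, 4), seed = seed),
    file.path(dir, "map_random.yaml")))
  add(write_exposure_map(make_staggered_map(c(8, 8), 5, 1),
                         file.path(dir, "map_uniform.yaml")))
  invisible(paths)
}
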