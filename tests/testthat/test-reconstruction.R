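staggered_groups <- function(trace, te = 4, k = 4, noise = NULL, seed = NULL) {
  lapply(seq_len(k) - 1, function(j) {
    sample_pixel(trace, exposure_config(te, delta = j * te / k), noise,
                 seed = if (is.null(seed)) NULL else seed + j)
  })
}

test_that("sub-ROI averaging equals the pixel for single-pixel masks and the mean otherwise", {
  p <- default_preset()
  tr <- spike_train(20, p, 30, duration = 60, dt = 0.05)
  sc <- soma_scene(tr, c(4, 4), radius = 10)  # every pixel carries the trace
  sm <- sample_scene(sc, make_staggered_map(c(4, 4), 5, 4))
  one <- matrix(FALSE, 4, 4); one[1, 1] <- TRUE
  s1 <- subroi_series(sm, one)
  expect_length(s1, 1)
  g <- sm$groups[[which(vapply(sm$groups, function(g) 1L %in% g$pixels, TRUE))]]
  expect_equal(s1[[1]]$value, g$values[which(g$pixels == 1L), ])
  # identical noiseless pixels: group average equals any single pixel
  all_mask <- matrix(TRUE, 4, 4)
  sall <- subroi_series(sm, all_mask)
  for (s in sall) expect_lt(max(abs(s$value - mean(s$value[1]) * 0 - s$value)), 1e-12)
  for (i in seq_along(sall)) {
    expect_equal(sall[[i]]$value, sm$groups[[i]]$values[1, ], tolerance = 1e-12)
  }
  expect_error(subroi_series(sm, matrix(FALSE, 4, 4)), "empty")
})

test_that("averaging n i.i.d.-noise pixels shrinks the noise std by about 1/sqrt(n)", {
  p <- default_preset()
  tr <- spike_train(numeric(0), p, 20, duration = 3000, dt = 0.1)
  sc <- soma_scene(tr, c(4, 4), radius = 10)
  sm <- sample_scene(sc, make_staggered_map(c(4, 4), 5, 1), default_noise(),
                     seed = 8)
  roi16 <- subroi_series(sm, matrix(TRUE, 4, 4))[[1]]
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  roi1 <- subroi_series(sm, one)[[1]]
  ratio <- sd(roi1$value) / sd(roi16$value)
  expect_gt(ratio, 4 * 0.85)
  expect_lt(ratio, 4 * 1.15)
})

test_that("band-pass conditioning uses 90% of Nyquist and suppresses DC", {
  s200 <- sampled_series(seq(5, 1000, by = 5), rnorm(200), exposure_config(5))
  f <- bandpass_condition(s200)
  expect_s3_class(f, "sampled_series")
  # DC input is attenuated by more than 40 dB away from the filter edges
  dc <- sampled_series(seq(5, 20000, by = 5), rep(7, 4000), exposure_config(5))
  out <- bandpass_condition(dc)
  expect_lt(max(abs(out$value[800:3200])), 7 * 0.01)
  # explicit cutoffs: 90 Hz at 200 Hz sampling, 360 Hz at 800 Hz sampling
  expect_equal(0.9 * 200 / 2, 90)
  expect_equal(0.9 * 800 / 2, 360)
  expect_error(bandpass_condition(s200, high_hz = 120), "pass-band")
})

test_that("stacked problems concatenate group matrices on a shared grid", {
  p <- default_preset()
  tr <- spike_train(30, p, 25, duration = 80, dt = 0.05)
  gs <- staggered_groups(tr, te = 5)
  prob <- stack_problem(gs, length(tr$values), tr$dt, lambda = 1)
  expect_equal(nrow(prob$e), sum(vapply(gs, function(g) length(g$value), 1L)))
  expect_equal(length(prob$y), nrow(prob$e))
  one <- stack_problem(gs[1], length(tr$values), tr$dt, lambda = 1)
  direct <- build_sampling_matrix(gs[[1]]$config, length(tr$values), tr$dt)
  expect_equal(one$e, direct, ignore_attr = TRUE)
  # merged end-times form a uniform 1.25 ms ladder
  ends <- sort(unlist(lapply(gs, `[[`, "time_ms")))
  expect_true(all(abs(diff(ends) - 1.25) < 1e-9))
})

test_that("ridge closed form matches an independent conjugate-gradient solver", {
  set.seed(31)
  p <- default_preset()
  tr <- spike_train(c(25, 50), p, 25, duration = 100, dt = 0.25)
  gs <- staggered_groups(tr, noise = default_noise(), seed = 300)
  prob <- stack_problem(gs, length(tr$values), 0.25, lambda = 50)
  v <- ridge_solve(prob)$value
  v_cg <- cg_ridge_oracle(prob$e, prob$y, prob$lambda)
  expect_lt(max(abs(v - v_cg)) / max(abs(v)), 1e-8)
})

test_that("ridge with square invertible E and lambda 0 recovers the signal exactly", {
  set.seed(30)
  tr <- fine_grid_trace(runif(12, 5, 30), dt = 5)  # coarse grid: dt = t_exp
  g <- sample_pixel(tr, exposure_config(5))
  prob <- stack_problem(list(g), length(tr$values), 5, lambda = 0)
  expect_equal(dim(prob$e), c(length(tr$values), length(tr$values)))
  v <- ridge_solve(prob)$value
  expect_equal(v, tr$values, tolerance = 1e-9)
})

test_that("very large ridge weights reduce to up-sampling by E'y", {
  p <- default_preset()
  tr <- spike_train(30, p, 25, duration = 80, dt = 0.25)
  gs <- staggered_groups(tr)
  prob <- stack_problem(gs, length(tr$values), 0.25, lambda = 1e9)
  v <- ridge_solve(prob)$value
  ety <- as.numeric(crossprod(prob$e, prob$y))
  cosine <- sum(v * ety) / sqrt(sum(v^2) * sum(ety^2))
  expect_gt(cosine, 0.999)
})

test_that("the ridge solution varies continuously in lambda and errors helpfully at 0", {
  p <- default_preset()
  tr <- spike_train(30, p, 25, duration = 60, dt = 0.25)
  gs <- staggered_groups(tr)
  prob1 <- stack_problem(gs, length(tr$values), 0.25, lambda = 10)
  prob2 <- stack_problem(gs, length(tr$values), 0.25, lambda = 10.01)
  d <- max(abs(ridge_solve(prob1)$value - ridge_solve(prob2)$value))
  expect_lt(d, 1e-3 * max(abs(ridge_solve(prob1)$value)))
  prob0 <- stack_problem(gs, length(tr$values), 0.25, lambda = 0)
  expect_error(ridge_solve(prob0), "lambda > 0")
})

test_that("noiseless staggered groups interpolate to the fast-pixel series", {
  p <- default_preset()
  tr <- spike_train(c(30, 55), p, 25, duration = 120, dt = 0.05)
  gs <- staggered_groups(tr, te = 5, k = 4)
  roi <- upsample_interpolate(gs, target_rate_hz = 800)
  fast <- sample_pixel(tr, exposure_config(5, t_sample = 1.25))
  shared <- intersect(round(roi$time_ms, 6), round(fast$time_ms, 6))
  expect_gt(length(shared), 50)
  a <- roi$value[match(shared, round(roi$time_ms, 6))]
  b <- fast$value[match(shared, round(fast$time_ms, 6))] / 5
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("a single group interpolates linearly and target rates are capped", {
  p <- default_preset()
  tr <- spike_train(30, p, 25, duration = 80, dt = 0.1)
  g <- sample_pixel(tr, exposure_config(5))
  roi <- upsample_interpolate(list(g), 200)
  expect_equal(roi$value, g$value / 5, tolerance = 1e-12)
  expect_error(upsample_interpolate(list(g), 400), "exceeds")
})

test_that("a fast spike train reconstructs at 1000 Hz with 8 samples between peaks", {
  p4 <- scaled_preset(4)
  spikes <- c(120, 128, 136)
  tr <- spike_train(spikes, p4, 100, duration = 400, dt = 0.1)
  gs <- lapply(0:3, function(j) sample_pixel(tr, exposure_config(4, delta = j)))
  roi <- upsample_interpolate(gs, 1000)
  pk <- sapply(spikes, function(st) {
    sel <- which(abs(roi$time_ms - st) <= 4)
    sel[which.max(roi$value[sel])]
  })
  expect_equal(diff(pk), c(8, 8))
})

test_that("multi-speed fusion conditions each group at its own bandwidth and keeps slow signals", {
  # per-group low-pass cutoffs at 90% of each Nyquist
  rates <- c(520, 260, 130, 65)
  expect_equal(round(0.9 * rates / 2), c(234, 117, 58, 29))
  # a 5 Hz sinusoid inside every pass-band survives fusion within 10%
  dt <- 0.1
  t <- seq(0, 12000 - dt, by = dt)
  vals <- 50 + 10 * sin(2 * pi * 5 * t / 1000)
  tr <- fine_grid_trace(vals, dt)
  gs <- lapply(c(1.9, 3.8, 7.7, 15.4), function(te) {
    sample_pixel(tr, exposure_config(round(te / dt) * dt))
  })
  expect_warning(fused <- multispeed_fuse(gs, target_rate_hz = 500),
                 "not uniform")  # distinct-speed ladders merge irregularly
  mid <- fused$time_ms > 4000 & fused$time_ms < 8000
  amp <- (max(fused$value[mid]) - min(fused$value[mid])) / 2
  expect_gt(amp, 10 * 0.9 / 1)
  expect_lt(amp, 10 * 1.1)
  # constant signal passes through as a constant (zero after high-pass)
  const <- lapply(c(2, 4), function(te) {
    sample_pixel(fine_grid_trace(rep(30, 120000), dt), exposure_config(te))
  })
  fc <- multispeed_fuse(const, 250)
  midc <- fc$time_ms > 4000 & fc$time_ms < 8000
  expect_lt(max(abs(fc$value[midc])), 0.3)  # 30 e-/ms baseline removed
})

test_that("interpolating uncorrelated pixels approximates their average", {
  set.seed(77)
  l <- 256
  smooth <- function() as.numeric(stats::filter(rnorm(l + 40), rep(1 / 12, 12),
                                                sides = 1))[41:(l + 40)]
  vs <- replicate(4, smooth())
  dt <- 1
  gs <- lapply(0:3, function(j) {
    sample_pixel(fine_grid_trace(vs[, j + 1] - min(vs) + 1, dt),
                 exposure_config(4, delta = j))
  })
  prob <- stack_problem(gs, l, dt, lambda = 1e7)
  vhat <- ridge_solve(prob)$value
  avg <- rowMeans(vs - min(vs) + 1)
  keep <- 20:(l - 20)
  expect_gt(cor(vhat[keep], avg[keep]), 0.9)
})

test_that("reconstruction adds little out-of-band energy for band-limited input", {
  dt <- 0.05
  t <- seq(0, 2000 - dt, by = dt)
  vals <- 50 + 5 * sin(2 * pi * 20 * t / 1000) + 3 * sin(2 * pi * 45 * t / 1000)
  tr <- fine_grid_trace(vals, dt)
  gs <- lapply(0:3, function(j) sample_pixel(tr, exposure_config(5, delta = 1.25 * j)))
  roi <- upsample_interpolate(gs, 800)
  x <- roi$value - mean(roi$value)
  sp <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) / length(x) * 800
  inband <- f <= 60 | f >= 800 - 60
  expect_lt(sum(sp[!inband]) / sum(sp), 0.01)
})

test_that("a spike missed by one phase is rescued by the others in the fused series", {
  p4 <- scaled_preset(4)
  te <- 8
  # worst-case placement for phase 0: the spike whose energy splits most
  # evenly across two consecutive phase-0 windows
  phase0_peak <- function(st) {
    tr <- spike_train(st, p4, 100, duration = 240, dt = 0.1)
    max(sample_pixel(tr, exposure_config(te))$value)
  }
  cand <- seq(100, 108, by = 0.5)
  spike_at <- cand[which.min(vapply(cand, phase0_peak, 1.0))]
  tr <- spike_train(spike_at, p4, 100, duration = 240, dt = 0.1)
  gs <- lapply(0:3, function(j) sample_pixel(tr, exposure_config(te, delta = 2 * j)))
  base <- 100 * te
  peak_per_phase <- vapply(gs, function(g) max(g$value) - base, 1.0)
  best_possible <- max(sample_pixel(tr, exposure_config(te, t_sample = 0.5))$value) - base
  expect_lt(peak_per_phase[1], 0.75 * best_possible)     # phase 0 under-samples it
  expect_gt(max(peak_per_phase[-1]), 0.70 * best_possible)  # another phase captures it
  roi <- upsample_interpolate(gs, 500)
  # rate units: spike amplitude ~ 10 e-/ms; one SNR unit of 1 e-/ms makes the
  # threshold-5 detection a >= 5 e-/ms amplitude requirement
  ev <- detect_spikes(roi, noise_sd = 1, burn_in_ms = 40)
  expect_true(any(abs(ev$time_ms - spike_at) < te))
})
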