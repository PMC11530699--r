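test_that("staggered maps assign the four canonical offsets in every 2x2 block", {
  m <- make_staggered_map(c(8, 8), t_exp = 5, n_phases = 4)
  expect_setequal(unique(as.numeric(m$delta)), c(0, 1.25, 2.5, 3.75))
  for (r in seq(1, 7, by = 2)) for (cl in seq(1, 7, by = 2)) {
    expect_setequal(as.numeric(m$delta[r:(r + 1), cl:(cl + 1)]),
                    c(0, 1.25, 2.5, 3.75))
  }
  expect_identical(m$layout, "staggered")
  u <- make_staggered_map(c(4, 4), 5, n_phases = 1)
  expect_true(all(u$delta == 0))
  expect_identical(u$layout, "uniform")
})

test_that("multispeed maps tile four exposures with the expected per-pixel rates", {
  ex <- c(1.9, 3.8, 7.7, 15.4)
  m <- make_multispeed_map(c(6, 6), ex)
  expect_setequal(unique(as.numeric(m$t_exp)), ex)
  for (r in seq(1, 5, by = 2)) for (cl in seq(1, 5, by = 2)) {
    expect_setequal(as.numeric(m$t_exp[r:(r + 1), cl:(cl + 1)]), ex)
  }
  rates <- sort(1000 / ex)
  expect_equal(rates, c(64.9, 129.9, 263.2, 526.3), tolerance = 1e-3)
  expect_identical(make_multispeed_map(c(4, 4), rep(5, 4))$layout, "uniform")
})

test_that("random maps permute configurations reproducibly", {
  base <- make_multispeed_map(c(6, 6), c(1, 2, 4, 8))
  r1 <- make_random_map(base, seed = 4)
  r2 <- make_random_map(base, seed = 4)
  expect_identical(r1$t_exp, r2$t_exp)
  expect_setequal(as.numeric(table(r1$t_exp)), as.numeric(table(base$t_exp)))
  expect_identical(r1$layout, "random")
})

test_that("exposure maps round-trip through YAML byte-identically", {
  d <- withr::local_tempdir()
  m <- make_staggered_map(c(4, 6), t_exp = 5, n_phases = 4)
  p1 <- file.path(d, "m1.yaml"); p2 <- file.path(d, "m2.yaml")
  write_exposure_map(m, p1)
  m2 <- read_exposure_map(p1)
  expect_equal(m2$t_exp, m$t_exp)
  expect_equal(m2$delta, m$delta)
  expect_identical(m2$layout, m$layout)
  write_exposure_map(m2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a uniform map on a static scene reproduces identical frames", {
  p <- default_preset()
  tr <- spike_train(numeric(0), p, 30, duration = 40, dt = 0.1)
  sc <- soma_scene(tr, c(4, 4), radius = 1.5, background = 10)
  sm <- sample_scene(sc, make_staggered_map(c(4, 4), 5, 1))
  fr <- assemble_frames(sm)
  for (k in 2:length(fr$times)) {
    expect_identical(fr$frames[, , k], fr$frames[, , 1])
  }
})

test_that("electron totals on a static scene are phase invariant and match the integral", {
  p <- default_preset()
  tr <- spike_train(numeric(0), p, 30, duration = 40, dt = 0.05)
  sc <- soma_scene(tr, c(4, 4), radius = 1.5, background = 10)
  totals <- sapply(c(0, 1.25), function(off) {
    m <- make_staggered_map(c(4, 4), 5, 4, base_offset = off)
    sm <- sample_scene(sc, m)
    # per pixel: electrons per sample * number of samples; compare the mean
    # electron rate against the direct time integral
    sum(vapply(sm$groups, function(g) sum(g$values), 1.0)) /
      sum(vapply(sm$groups, function(g) length(g$times) * length(g$pixels), 1.0))
  })
  expect_equal(totals[1], totals[2], tolerance = 1e-12)
  px_rates <- sc$intensity[, , 1]
  expect_equal(totals[1], mean(px_rates) * 5, tolerance = 1e-9)
})

test_that("scene sampling is seed deterministic and validates shapes", {
  p <- default_preset()
  tr <- spike_train(10, p, 30, duration = 30, dt = 0.05)
  sc <- soma_scene(tr, c(4, 4), radius = 1.5, background = 10)
  m <- make_staggered_map(c(4, 4), 5, 4)
  a <- sample_scene(sc, m, default_noise(), seed = 21)
  b <- sample_scene(sc, m, default_noise(), seed = 21)
  expect_identical(a$groups[[2]]$values, b$groups[[2]]$values)
  expect_error(sample_scene(sc, make_staggered_map(c(8, 8), 5, 4)), "shape")
})

test_that("sub-frame splitting yields quarter videos that interleave to the full stream", {
  p <- default_preset()
  tr <- spike_train(numeric(0), p, 30, duration = 200, dt = 0.1)
  sc <- soma_scene(tr, c(6, 6), radius = 2, background = 10)
  m <- make_staggered_map(c(6, 6), t_exp = 40, n_phases = 4,
                          base_offset = 0)  # offsets 0, 10, 20, 30 ms
  sm <- sample_scene(sc, m)
  sub <- split_subframes(sm)
  expect_length(sub, 4)
  for (g in sub) {
    expect_equal(dim(g$frames)[1:2], c(3, 3))
    expect_equal(g$rate_hz, 25)
  }
  il <- interleave_subframes(sub)
  expect_equal(il$rate_hz, 100)           # interleaved period 10 ms
  expect_equal(diff(sort(unique(il$times)))[1], 10)
  # round trip: the interleaved stream covers every group's frames once
  expect_equal(sort(table(il$group)), sort(sapply(sub, function(g) length(g$times))),
               ignore_attr = TRUE)
  # n_phases = 1 keeps the full grid in one group
  one <- split_subframes(sample_scene(sc, make_staggered_map(c(6, 6), 40, 1)))
  expect_length(one, 1)
  expect_equal(dim(one[[1]]$frames)[1:2], c(6, 6))
})

test_that("box downsampling has DC gain one and matches the long-exposure oracle", {
  p <- default_preset()
  tr <- spike_train(c(40, 90), p, 25, duration = 200, dt = 0.05)
  s800 <- sample_pixel(tr, exposure_config(1.25))
  expect_identical(box_downsample(s800, 1), s800)
  const <- sample_pixel(fine_grid_trace(rep(8, 4000), 0.05), exposure_config(1.25))
  d <- box_downsample(const, 4)
  expect_true(all(abs(d$value - 8 * 1.25) < 1e-10))
  # 800 Hz boxed by 4 == direct 5 ms exposure sampling, up to the window
  # equivalence 4 x 1.25 ms = 5 ms (values are window means vs integrals)
  d4 <- box_downsample(s800, 4)
  s200 <- sample_pixel(tr, exposure_config(5))
  expect_equal(d4$time_ms, s200$time_ms)
  expect_lt(max(abs(d4$value * 4 - s200$value)), 1e-10)
  expect_error(box_downsample(sampled_series(1.25, 3, exposure_config(1.25)), 4),
               "shorter")
})
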