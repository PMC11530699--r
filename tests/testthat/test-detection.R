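test_that("noise estimation recovers the high-passed std of white noise", {
  set.seed(10)
  fs <- 800
  sigma <- 3
  x <- rnorm(8 * fs, sd = sigma)
  est <- estimate_noise(x, fs_hz = fs)
  frac <- zero_phase_hp_energy_fraction(fs, 50)
  expect_lt(abs(est - sigma * frac) / (sigma * frac), 0.10)
  expect_equal(estimate_noise(rep(4, 3 * fs), fs_hz = fs), 0, tolerance = 1e-9)
  expect_error(estimate_noise(rnorm(fs), fs_hz = fs), "shorter")
})

test_that("the spike-free window shields the estimate from large spikes", {
  set.seed(11)
  fs <- 400
  x <- rnorm(10 * fs)
  clean <- estimate_noise(x, fs_hz = fs)
  spiky <- x
  spike_idx <- seq(7 * fs, 9.5 * fs, by = fs %/% 4)
  for (i in spike_idx) spiky[i:(i + 3)] <- spiky[i:(i + 3)] + 40
  est <- estimate_noise(spiky, fs_hz = fs)
  expect_lt(abs(est - clean) / clean, 0.05)
  # manual window override
  manual <- estimate_noise(spiky, fs_hz = fs, window_ms = c(1000, 4000))
  expect_lt(abs(manual - clean) / clean, 0.10)
})

test_that("detection finds planted spikes at their times and nothing in pure noise", {
  set.seed(12)
  fs <- 800
  dur_s <- 12
  n <- dur_s * fs
  t_ms <- (seq_len(n) - 1) / fs * 1000
  noise <- rnorm(n)
  spike_times <- seq(1000, 10900, by = 1100)
  shape <- spike_waveform(seq(-15, 30, by = 1000 / fs), scaled_preset(6)) / 0.1
  x <- noise
  for (st in spike_times) {
    i0 <- which.min(abs(t_ms - (st - 15)))
    idx <- i0 + seq_along(shape) - 1
    x[idx] <- x[idx] + 8 * shape
  }
  nsd <- estimate_noise(noise, fs_hz = fs)
  ev <- detect_spikes(x, nsd, fs_hz = fs, burn_in_ms = 300)
  for (st in spike_times) {
    expect_lte(min(abs(ev$time_ms - st)), 2 * 1000 / fs + 1e-9)
  }
  # every event is attributable to a planted spike
  expect_true(all(sapply(ev$time_ms, function(te) any(abs(spike_times - te) <= 15))))
  ev0 <- detect_spikes(noise, nsd, fs_hz = fs, burn_in_ms = 300)
  expect_equal(nrow(ev0), 0)
  expect_equal(nrow(detect_spikes(x, nsd, fs_hz = fs, threshold = Inf)), 0)
  expect_error(detect_spikes(x, 0, fs_hz = fs), "noise_sd")
})

test_that("detection is invariant to common rescaling of series and noise", {
  set.seed(13)
  fs <- 400
  x <- rnorm(4 * fs)
  x[c(600, 900, 1300)] <- x[c(600, 900, 1300)] + 10
  nsd <- estimate_noise(x, fs_hz = fs)
  e1 <- detect_spikes(x, nsd, fs_hz = fs)
  for (c_scale in c(0.01, 7, 1000)) {
    e2 <- detect_spikes(c_scale * x, c_scale * nsd, fs_hz = fs)
    expect_equal(e2$time_ms, e1$time_ms)
    expect_equal(e2$snr, e1$snr, tolerance = 1e-9)
  }
})

test_that("event matching reports the windowed peak of the comparison series", {
  set.seed(14)
  fs <- 800
  n <- 6 * fs
  x <- rnorm(n)
  x[seq(1200, 4000, by = 700)] <- 12
  nsd <- estimate_noise(x, fs_hz = fs)
  ev <- detect_spikes(x, nsd, fs_hz = fs, burn_in_ms = 200)
  same <- match_events(ev, x, nsd, fs_hz_b = fs)
  expect_equal(same$snr_b, same$snr, tolerance = 1e-9)
  # a 10 ms delayed copy is still matched inside the 30 ms window
  shift <- round(0.010 * fs)
  delayed <- c(rep(0, shift), x[1:(n - shift)])
  del <- match_events(ev, delayed, nsd, fs_hz_b = fs)
  expect_equal(del$snr_b, same$snr, tolerance = 0.15)
  # pure noise pairs fall below the detection threshold
  noise_pair <- match_events(ev, rnorm(n), 1, fs_hz_b = fs)
  expect_lt(stats::median(noise_pair$snr_b), 5)
})

test_that("match windows clipped at the series edge raise a warning", {
  fs <- 400
  ev <- data.frame(time_ms = 5, snr = 8)
  expect_warning(match_events(ev, rnorm(fs), 1, fs_hz_b = fs), "clipped")
})

test_that("the current-step protocol spans 600 to 0 pA in 40 pA steps of 200 ms", {
  pr <- current_step_protocol()
  expect_equal(nrow(pr), 16)
  expect_true(all(pr$duration_ms == 200))
  expect_equal(unique(diff(pr$amplitude_pa)), -40)
  expect_equal(range(pr$amplitude_pa), c(0, 600))
  gaps <- diff(pr$start_ms) - 200
  expect_true(all(gaps >= 200))
})

test_that("pulse SNR is zero for flat series and equals the step size in noise units", {
  fs <- 1000
  pr <- current_step_protocol(start_ms = 500, gap_ms = 300)
  n <- (max(pr$start_ms) + 600) * fs / 1000
  t_ms <- (seq_len(n) - 1) / fs * 1000
  flat <- rep(2, n)
  out <- pulse_snr(flat, pr, noise_sd = 1, fs_hz = fs)
  expect_true(all(out$pulse_snr == 0))
  sigma <- 0.5
  stepped <- flat
  for (i in seq_len(nrow(pr))) {
    inside <- t_ms >= pr$start_ms[i] & t_ms < pr$start_ms[i] + 200
    stepped[inside] <- stepped[inside] + 4 * sigma
  }
  out2 <- pulse_snr(stepped, pr, noise_sd = sigma, fs_hz = fs)
  expect_equal(out2$pulse_snr, rep(4, 16), tolerance = 1e-9)
  bad <- pr; bad$start_ms[2] <- bad$start_ms[1] + 250
  expect_error(pulse_snr(stepped, bad, noise_sd = sigma, fs_hz = fs), "flanks")
})

test_that("longer exposures give higher pulse SNR at matched photon budget", {
  # plateau response sampled with 5 ms vs 1.25 ms pixels, same scene
  set.seed(15)
  pr <- current_step_protocol(start_ms = 500, gap_ms = 300)[1:6, ]
  dur <- max(pr$start_ms) + 600
  dt <- 0.05
  t <- seq(0, dur - dt, by = dt)
  base <- 2
  v <- rep(base, length(t))
  for (i in seq_len(nrow(pr))) {
    v[t >= pr$start_ms[i] & t < pr$start_ms[i] + 200] <- base * 1.05
  }
  tr <- fine_grid_trace(v, dt)
  np <- noise_params(base, calibrate_read_noise(2.6, 0.9))
  snr_for <- function(te, seed) {
    s <- sample_roi_series(tr, exposure_config(te), np, n_pixels = 64, seed = seed)
    rate <- sampled_series(s$time_ms, s$value / te, s$config)
    nsd <- estimate_noise(rate)
    median(pulse_snr(rate, pr, nsd)$pulse_snr)
  }
  slow <- median(sapply(1:5, function(s) snr_for(5, 100 + s)))
  fast <- median(sapply(1:5, function(s) snr_for(1.25, 200 + s)))
  expect_gt(slow, fast)
})

test_that("paired event comparison reports medians and a rank-sum p-value", {
  set.seed(16)
  m <- data.frame(snr = 6 + rexp(30), snr_b = 3 + rexp(30))
  out <- compare_event_snr(match_events(
    detect_spikes(c(rep(0, 100), 10, rep(0, 100)), 1, fs_hz = 100),
    c(rep(0, 100), 5, rep(0, 100)), 1, fs_hz_b = 100))
  expect_equal(out$n, 1)
  full <- compare_event_snr(m)
  expect_equal(full$n, 30)
  expect_lt(full$p_value, 0.05)
  expect_gt(full$median_ratio, 1)
})
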