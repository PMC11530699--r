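# Shared fixtures and small independent oracles for the test suite.

default_preset <- function() gevi_preset("asap3")

default_noise <- function() noise_params(baseline_rate = 20,
                                         n0 = calibrate_read_noise(2.6, 0.9))

# Spike shape with all time constants scaled to a target half-width.
scaled_preset <- function(target_hw, peak_dff = 0.1) {
  base <- gevi_preset("asap3", peak_dff = peak_dff)
  s <- target_hw / half_width(base)
  gevi_spike_params(base$tau_rf * s, base$tau_rs * s,
                    base$tau_ff * s, base$tau_fs * s,
                    base$a_r, base$b_r, base$a_f, base$b_f,
                    peak_dff = peak_dff)
}

# Direct-convolution oracle: integrate values over [end - t_exp, end) windows
# by explicit summation (independent of the package's cumsum path).
window_sums_oracle <- function(values, dt, config) {
  total <- length(values) * dt
  m_min <- max(1, ceiling((config$t_exp - config$delta) / config$t_sample - 1e-9))
  m_max <- floor((total - config$delta) / config$t_sample + 1e-9)
  k <- round(config$t_exp / dt)
  sapply(m_min:m_max, function(m) {
    e <- round((config$delta + m * config$t_sample) / dt)
    sum(values[(e - k + 1):e]) * dt
  })
}

# Conjugate-gradient solver for (E'E + lambda I) v = E'y, independent of
# the closed-form path in ridge_solve().
cg_ridge_oracle <- function(e, y, lambda, tol = 1e-14, maxit = 10000) {
  amul <- function(v) crossprod(e, e %*% v) + lambda * v
  b <- crossprod(e, y)
  x <- numeric(ncol(e))
  r <- b - amul(x)
  p <- r
  rs <- sum(r^2)
  for (i in seq_len(maxit)) {
    ap <- amul(p)
    alpha <- rs / sum(p * ap)
    x <- x + alpha * p
    r <- r - alpha * as.numeric(ap)
    rs_new <- sum(r^2)
    if (sqrt(rs_new) < tol * sqrt(sum(b^2))) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  as.numeric(x)
}

# Energy fraction of the zero-phase (forward-backward) 4th-order Butterworth
# high-pass on white noise: mean of |H|^4 over the band, via signal::freqz.
zero_phase_hp_energy_fraction <- function(fs_hz, cutoff_hz, n = 4096) {
  ba <- signal::butter(4, cutoff_hz / (fs_hz / 2), type = "high")
  h <- signal::freqz(ba$b, ba$a, n = n)
  sqrt(mean(Mod(h$h)^4))
}
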