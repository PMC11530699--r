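# pepix

Simulation and reconstruction toolkit for image sensors with **pixel-wise
programmable exposure**, aimed at high-speed fluorescence voltage imaging.

## The problem

Genetically encoded voltage indicators (GEVIs) report action potentials as
~6 ms-wide fluorescence transients of ~10 % dF/F. A conventional camera must
pick one exposure for all pixels: short exposures (e.g. 1.25 ms at 800 Hz)
resolve spikes but are noisy; long exposures (5 ms at 200 Hz) collect more
photons and less read noise but alias spikes away. When each pixel's
exposure duration and phase are individually programmable, the pixels inside
one region of interest (ROI) can all integrate for the SNR-optimal duration
*and*, staggered in phase, jointly sample the ROI at a high equivalent rate.
`pepix` provides the models and algorithms for designing and analyzing such
acquisitions, for sensor designers and imaging methodologists.

At its core are four pieces, in the field's standard notation:

* **Spike model** — a double-exponential waveform
  `v(t) = A_R e^{t/τ_Rf} + B_R e^{t/τ_Rs}` (t < 0),
  `A_F e^{-t/τ_Ff} + B_F e^{-t/τ_Fs}` (t ≥ 0), normalized to a chosen
  peak dF/F.
* **Sampling model** — each sample integrates a box window of duration
  `T_E` at phase `Δ` (`y = E v` with a sampling matrix `E`), with Poisson
  shot noise (`N_shot = max{y} + F·T_E`) and thermal read noise
  (`N_read = N0 / T_E`).
* **SNR model** — `SNR(T_E) = max{y} / sqrt(N0/T_E + max{y} + F·T_E)`,
  with the exposure that maximizes it found by grid search.
* **Reconstruction** — staggered pixel groups are fused into one high-rate
  ROI series either by the ridge closed form
  `v̂ = (EᵀE + λI)⁻¹ Eᵀy` or by its large-λ limit, merge-and-linear
  interpolation; the averaged spectrum of `K` staggered phases provably
  equals that of one pixel sampled `K` times faster, which is why aliasing
  disappears.

Downstream analysis (noise estimation from a spike-free window, SNR > 5
putative-spike detection, 30 ms cross-sensor event matching, current-step
pulse SNR) matches the standard voltage-imaging workflow.

## Worked example

```r
library(pepix)

# An ASAP3-like spike and the default noise model (F = 20 e-/ms,
# read noise 2.6 e- rms at the 0.9 ms readout period)
p  <- gevi_preset("asap3")
np <- noise_params(baseline_rate = 20, n0 = calibrate_read_noise(2.6, 0.9))

half_width(p)                                              # 5.99 ms
snr_at_exposure(p, np, 5) / snr_at_exposure(p, np, 1.25)   # 1.77
optimal_exposure(p, np)                                    # 12.6 ms

# Four 200 Hz pixel groups staggered by 1.25 ms cover an ROI at 800 Hz
cfgs <- lapply(0:3, function(k) exposure_config(5, delta = 1.25 * k))
effective_rate(cfgs)                                       # 800 Hz

# End-to-end: dim culture scene, staggered sampling, reconstruction,
# spike detection
out <- run_scenario(scenario_staggered_culture(seed = 1))
nrow(out$events)              # 27 putative events above SNR 5
median(out$events$snr)        # 7.6
head(out$events, 3)
#>   time_ms       snr
#> 1  503.75 10.282032
#> 2  972.50  5.413972
#> 3  978.75  7.587344
```

Reading the numbers: the spike half-width matches the ~6 ms figure typical
of ASAP3 action potentials; quadrupling the exposure from 1.25 ms to 5 ms
raises the modeled peak-sample SNR by a factor 1.77 (the analytic
peak-sample model; the end-to-end pipeline gains more because slow pixels
are also filtered to a narrower noise band); the analytic optimum sits past
the half-width because the spike's slow tail keeps paying under baseline
shot-noise growth. The scenario run simulates 10 s of spiking at 20 planted
spikes, reconstructs an 800 Hz ROI series from four staggered 200 Hz phase
groups, and detects events — a handful of the 27 events are secondary peaks
within spike tails; all 20 planted spikes are among them.

A thin command-line front end over the same functions ships in
`inst/cli/pepix` (`design`, `spectra`, `simulate`, `reconstruct`, `analyze`,
`run`).

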