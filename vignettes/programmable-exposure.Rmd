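---
title: "Modeling pixel-wise programmable exposure for voltage imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pixel-wise programmable exposure for voltage imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepix)
```

## The problem

Genetically encoded voltage indicators (GEVIs) report membrane potential as
millisecond-scale fluorescence transients, typically ~10 % dF/F and ~6 ms
wide at half maximum. Capturing them with a camera forces a trade-off: short
pixel exposures give the temporal resolution to separate spikes but collect
few photons and suffer high read noise; long exposures improve the
signal-to-noise ratio (SNR) but sample below the Nyquist rate of the signal
and alias spikes away. A sensor whose pixels each have a *programmable*
exposure duration and phase escapes the trade-off for spatially redundant
scenes: several pixels inside one region of interest (ROI) can integrate for
a long time *and*, staggered in phase, jointly sample the ROI at a high
equivalent rate. `pepix` simulates such sensors and implements the analysis
that goes with them: waveform generation, exposure sampling with a physical
noise model, an analytic SNR-versus-exposure model, the sampling theory of
phase-staggered ensembles, reconstruction of high-rate ROI series, and spike
detection.

## Spike waveform model

A GEVI spike is modelled as two double-exponential branches meeting at the
peak (time 0):

$$
v(t) =
\begin{cases}
A_R e^{t/\tau_{Rf}} + B_R e^{t/\tau_{Rs}}, & t < 0,\\
A_F e^{-t/\tau_{Ff}} + B_F e^{-t/\tau_{Fs}}, & t \ge 0,
\end{cases}
$$

with a fast and a slow time constant on each branch. The constructor
rescales the falling amplitudes so both branches agree at the peak, then
normalizes the whole waveform so its maximum equals `peak_dff` (default
10 %). Three named presets are shipped. Their time constants are package
defaults, not published values (the indicator papers report kinetics in
their own supplements): the `asap3` preset is constrained to the ~6 ms
half-width reported for cultured-neuron action potentials with that
indicator, while `archon` and `voltron` are faster, and all three were
chosen so that the SNR model's optimal exposure (below) behaves as expected
for fast indicators.

```{r presets}
sapply(c("asap3", "archon", "voltron"),
       function(nm) half_width(gevi_preset(nm)))
```

Ground-truth traces carry photoelectron-rate units (e-/ms):
`spike_train()` returns `baseline_rate * (1 + sum of spikes in dF/F)`, so
integrating a trace over an exposure window yields electrons. Spikes are
generated positive-going; indicators with negative-going raw polarity are
handled by a sign flag, and detection always assumes the positive-going
convention (series from such indicators are inverted before analysis, the
usual practice).

## Exposure sampling and the noise model

A pixel with exposure $T_E$, sample period $T_S$ (default $T_S = T_E$:
back-to-back exposure) and phase offset $\Delta$ produces sample $m$ by
integrating the window $[\Delta + mT_S - T_E, \Delta + mT_S)$; the sample is
timestamped at the *end* of its window, the instant the pixel is read out.
An optional re-centering to window midpoints exists in the interpolation
path because a consumer may prefer mid-window stamps; end-of-window is the
default throughout. On the fine grid this is a box kernel of $T_E/dt$ taps
of weight $dt$ (`exposure_kernel()`), or, stacked over samples, the sampling
matrix $E$ of `build_sampling_matrix()`.

Noise has two sources:

* **Shot noise** — the electron count of each sample is drawn from a
  Poisson distribution whose rate equals the noiseless count (signal plus
  baseline), so its variance equals its mean.
* **Read noise** — zero-mean Gaussian with variance $N_0 / T_E$: thermal
  noise integrated over the readout bandwidth $1/T_E$, so slower pixels read
  out more quietly. $N_0$ has units e-² ms and is calibrated from a quoted
  rms figure with `calibrate_read_noise(rms_e, t_ref_ms)`; the default is
  2.6 e- rms at a 0.9 ms readout period, giving $N_0 = 6.084$ e-² ms.

Two unit conventions deserve emphasis because the source material leaves
them open. First, the baseline fluorescence $F$ is treated as a *rate* in
e-/ms, so the baseline shot-noise power over one exposure is $F \cdot T_E$
electrons. Second, the read-noise density is referenced to the sensor's
readout period (0.9 ms), not to any particular exposure. Both choices are
exposed as plain parameters, so other readings cost one argument. ADC
quantization is not modelled (a uniform quantizer adds noise well below
the shot noise at realistic gains), and neither are dark current,
fixed-pattern noise, or pixel crosstalk.

`sample_roi_series()` simulates the average of $n$ identical pixels through
its exact sufficient statistic (summed Poisson counts, averaged Gaussian
read noise), which keeps large-ROI simulations cheap without changing the
law of the result; `sample_scene()` samples every pixel individually for
scene-level work.

## SNR versus exposure

The peak-sample SNR of a spike under exposure $T_E$ is

$$
\mathrm{SNR}(T_E) = \frac{\max y}{\sqrt{N_0/T_E + \max y + F\,T_E}},
$$

where $\max y$ (`peak_response()`) is the best-phase windowed integral of
the spike's electron-rate transient — the largest electron count the spike
can contribute to one sample. Lengthening the exposure helps twice (more
signal electrons, less read noise) until the window outgrows the spike;
beyond that the signal saturates at the spike area while baseline shot
noise keeps growing as $\sqrt{F T_E}$, so the curve rises and then falls.
`optimal_exposure()` locates the argmax by grid search (default 0.1 ms
steps; curves can be non-smooth at kernel-quantization boundaries, so no
derivative method is used), breaking ties toward the shorter exposure.

Two quantitative notes on this model under its default parameters
($F = 20$ e-/ms, 10 % dF/F, $N_0$ as above), both verified by the test
suite and the acceptance script rather than asserted here:

* The modeled SNR ratio between 5 ms and 1.25 ms exposures computes to
  about 1.8 for the ~6 ms-wide `asap3` preset. A band of 2–3 fold is often
  quoted for this comparison; reaching it within this model requires either
  reading $F$ as electrons per exposure rather than a rate, or referencing
  the read-noise calibration to the long exposure. We keep the documented
  conventions and report the computed value as is. Notably, the *end-to-end*
  gain of the staggered configuration (below) does exceed 2, because the
  practical pipeline also narrows the noise bandwidth of slow pixels by
  filtering, which the peak-sample model does not capture.
* With the spike width pinned at ~6 ms, the argmax of the analytic curve
  falls near 12 ms, roughly twice the half-width — under $F\,T_E$ baseline
  growth the marginal signal of the spike's slow tail keeps paying until
  well past the half-width. The faster presets peak in the 4–8 ms band.
  A "optimal exposure ≈ half-width" summary is therefore accurate for the
  faster presets and an approximation for the slowest one.

## Why staggering defeats aliasing

A pixel sampling at period $T_E$ has the aliased spectrum
$Y_k(f) = \tfrac{1}{T_E}\sum_n E(f - n/T_E)\, e^{-j2\pi nk/K}$, where
$E(f)$ is the box exposure's transfer function (a sinc with exact nulls at
multiples of $1/T_E$) and $k$ indexes the pixel's phase among $K$ staggered
phases. Averaging the $K$ phase spectra cancels every replica whose index is
not a multiple of $K$ — the phase factors sum to zero — leaving replicas
spaced $K/T_E$ apart. The ensemble therefore behaves exactly like one pixel
sampled $K$ times faster with the same exposure; in the time domain, the
merged samples of the $K$ phases *are* the samples of that faster pixel,
which the tests assert to machine precision. Four phases at 200 Hz give an
800 Hz equivalent ROI rate; four phases at 25 Hz give a 100 Hz video.

What staggering does not fix: the exposure nulls themselves. A 4 ms
exposure suppresses 250 Hz and 500 Hz regardless of phase. Mixing pixels of
*different* exposure durations covers those notches
(`config_frequency_coverage()`), which is the rationale for the multi-speed
layout. The averaged spectrum here weights phases equally; a pixel-count
weighted variant is available as an argument for irregular ROIs, without any
claim beyond the equal-weight analysis.

Spectra are evaluated analytically on a frequency grid (default 0–1000 Hz,
0.5 Hz step, 16 replicas; the truncation error decays like $1/f$ since
$|E|$ does), so null locations are exact rather than FFT-limited.

## Reconstruction

Stacking every group's sampling matrix and measurement vector gives
$y = E\,v_{ROI} + \varphi$, solved as a ridge regression with closed form
$\hat v = (E^\top E + \lambda I)^{-1} E^\top y$ (`ridge_solve()`). Two paths
are deliberately exposed:

* the exact ridge solution, used as the reference and in tests (an
  independent conjugate-gradient solver cross-checks it);
* the practical path (`upsample_interpolate()`): normalize each group to
  rate units, merge by timestamp, linearly interpolate onto the target
  grid. This is the large-$\lambda$ limit of the ridge — as $\lambda$ grows
  the solution tends to a scaled $E^\top y$, i.e. up-sampling plus
  interpolation — and matches how the method is used in practice, where a
  deliberately large $\lambda$ under-fits noise rather than over-fitting it.
  The default $\lambda$ is $100 \times$ the mean diagonal of $E^\top E$.

Interpolating pixels that carry *uncorrelated* signals yields an
approximation proportional to their average (under-fitting features seen by
a single phase), which the suite reproduces on a synthetic construction:
reconstruction correlates > 0.9 with the true pixel average. This matters
because it bounds the artifact risk of interpolation on heterogeneous ROIs.

Per-group conditioning before merging uses a 4th-order Butterworth band-pass
(high-pass 0.5 Hz against photobleaching drift; low-pass at 90 % of each
group's own Nyquist frequency — 90 Hz for 200 Hz pixels, 360 Hz at 800 Hz,
and 234/117/58/29 Hz for the 520/260/130/65 Hz multi-speed groups). Filters
run forward-backward (zero phase) so that peak times are not skewed between
groups of different rates — a requirement for coherent timestamp merging;
the stated filter order refers to the underlying design, and the zero-phase
realization squares its magnitude response. The first and last stretch of a
heavily high-passed record carries filter edge transients; detection
accepts a `burn_in_ms` argument and the bundled scenarios exclude a few
hundred milliseconds at each end.

## Noise estimation and spike detection

One SNR unit is the standard deviation of a 50 Hz-high-passed, spike-free
stretch of at least 2 s. The spike-free stretch is chosen automatically as
the minimum-variance 2 s window of the 2 Hz-high-passed series (a manual
window override exists). Detection runs on the 2 Hz-high-passed series
divided by that unit: local maxima above threshold 5, de-duplicated within a
5 ms refractory window (chosen below the spike half-width; the procedure's
source is silent on de-duplication). Event matching against a second series
reports the highest SNR of that series within a 30 ms window centered on
each event, and `compare_event_snr()` summarizes paired events with medians
and a two-sided Wilcoxon rank-sum test (base R's `wilcox.test`).

## What the synthetic generator does and does not emulate

The generator covers: double-exponential spikes at controllable
inter-spike intervals, constant baselines, slow subthreshold components
(any fine-grid trace can be supplied), per-pixel Poisson shot noise,
exposure-dependent Gaussian read noise, and the staggered / tiled /
multi-speed / random pixel layouts. It does not emulate photobleaching
kinetics (removed by the 0.5 Hz high-pass in any case), indicator
photophysics such as the amplitude variations seen at stimulus offsets,
optical blur, motion, dark current or fixed-pattern noise. Passing tests
therefore demonstrate the sampling and reconstruction mathematics and the
direction and rough size of the SNR effects — not performance on real
recordings, where spatial inhomogeneity and sensor non-idealities enter.

The headline end-to-end comparison (staggered 5 ms, four phases, versus
uniform 1.25 ms sampling) is run under a dim-culture condition chosen once:
per-pixel baseline 1 e-/ms (1000 photoelectrons per second per pixel —
voltage imaging of dim membranes is read-noise-relevant at millisecond
exposures, which is the regime the method targets), 10 % dF/F spikes,
20 spikes over 10 s, and 2500-pixel groups. Both arms see the same scene and
photon budget, and the comparison pairs series built from equal pixel
counts per output sample — the fair-comparison construction in which the
reference camera's ROI is split into quarter sub-ROIs matching the phase
groups. Under these conditions the median paired spike-SNR gain of the
staggered arm computes to a little over 2. The gain shrinks toward 1 as
pixels get brighter (shot noise, which no exposure schedule can redistribute
at fixed photon budget, then dominates), so this figure is a statement about
the read-noise-limited regime, not a universal constant.

## Numerical choices

* Fine grid: 0.05 ms by default — it divides every exposure and offset used
  by the standard layouts (1.25, 2.5, 3.75, 5 ms, …); all exposure
  parameters must sit on the grid to within 1 ns, enforced loudly.
* SNR-model evaluation grid: 0.025 ms (divides 1.25 ms exactly).
* Exposure configs with $T_S < T_E$ (overlapping windows) are accepted as
  mathematical references — e.g. the faster single pixel that a staggered
  ensemble equals — while `exposure_map()` enforces $T_S \ge T_E$ for
  physical layouts.
* Degenerate inputs: zero noise with zero signal is an error in the SNR
  model; an all-false ROI mask, a singular normal-equations system at
  $\lambda = 0$, and a target rate above the merged equivalent rate are
  errors with instructions.
* Problem sizes in the tests and acceptance script are desk-scale by
  design: 10 s records, ROIs up to 100×100 pixels (simulated at group level
  through the sufficient statistic), ridge systems up to a few hundred
  unknowns. These sizes were chosen so the full suite runs in seconds while
  every Monte-Carlo tolerance still has comfortable margin.

## Known limitations

* The analytic SNR model scores only the peak sample; it ignores the
  filtering gain available to slow pixels downstream, and so under-predicts
  the end-to-end advantage of long exposures (see above).
* The hardware scheduling constraint that a real readout chain imposes on
  realizable phase offsets (one readout slot per column group per period)
  is not enforced; the simulator will happily produce maps a specific chip
  could not schedule.
* Linear interpolation between merged timestamps is exact only at shared
  sample instants; between them it is the first-order limit of the ridge
  path, not a band-limited reconstruction.
* The 1040 Hz-class equivalent rates quoted for mixed-speed layouts depend
  on how the merged, irregular timestamp ladder is summarized;
  `effective_rate()` reports the reciprocal median gap with a warning when
  the ladder is irregular rather than forcing a single number silently.
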