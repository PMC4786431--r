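---
title: "Quantifying burst-and-pause firing and dendritic calcium transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying burst-and-pause firing and dendritic calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstpause)
```

## The measurement problem

*Drosophila* larval class IV dendritic-arborization neurons are polymodal
nociceptors. Under focal step-like heating above roughly 43 °C they fire
high-frequency trains interrupted by silent intervals — "burst and pause"
firing — and their entire dendritic arbor shows large calcium transients
reported by a ratiometric FRET indicator (TN-XXL: calcium binding raises the
YFP/CFP emission ratio). Two derived quantities carry most of the
science: the count of *unconventional spikes* (USs), spike pairs far closer
together than ordinary firing allows, and the *total peak number*, a count
of discrete rises of the instantaneous firing rate. Both correlate with the
size of the dendritic calcium transient.

`burstpause` implements the full quantitative chain — spike-train metrics,
US classification, the FRET ratio pipeline, electrode-resistance
thermometry, and the supporting statistics — together with synthetic-data
generators that produce inputs with known ground truth, so every stage can
be validated end to end.

## Firing-rate metrics

**Windowed rates.** `windowed_rate()` slides a rectangular window of width
$\Delta t$ (default 400 ms) along the spike train; the rate at left edge $t$
is the spike count in $[t, t + \Delta t)$ divided by $\Delta t$.
`max_firing_rate()` returns the exact maximum over *all* real-valued window
placements: because the count is maximal for some placement whose left edge
coincides with a spike, evaluating the window at each spike time suffices.
This makes the implementation provably equal to a brute-force enumeration,
which the test suite checks on random trains. `time_to_max()` reports the
left edge, relative to stimulus onset, of the *earliest* placement attaining
the maximum (ties break early), the latency metric that separates slow- from
fast-onset thermoreceptor phenotypes. Window placements for the latency scan
are gridded at 1 ms; the latency of a discrete spike train is not defined
below the grid anyway.

**Spike density and derivative peaks.** `spike_density()` sums unit-area
Gaussian kernels ($\sigma$ = 25 ms by default) on a uniform grid. No
boundary correction is applied: kernel mass may leak outside the evaluated
range, so the time integral equals the spike count only when the range
extends a few $\sigma$ beyond the spikes — the test suite holds this to
0.1 %. `rate_derivative()` differentiates the curve on a 0.1 ms grid
(central differences).

`total_peak_number()` implements the burst-counting metric: locate local
maxima of the density derivative inside the stimulation window, set a
threshold at 0.5 of the *primal* peak, and count the maxima above it. Two
conventions needed fixing where the verbal description is ambiguous:

* **Primal peak.** We read "primal" literally as the *first* derivative
  peak of the response — the rise of the onset burst — and make that the
  default (`primal = "first"`); the largest peak is available via
  `primal = "max"`. For step-heating responses the onset burst is the
  strongest rise, and the two conventions coincide. For pulsatile
  optogenetic drive they do not: burst-to-burst variation in rise steepness
  means that under the "largest" convention even ideal five-burst trains
  lose peaks to the threshold, and the metric can no longer report five
  peaks for five pulses, which is the published behaviour of the metric and
  the intuitive meaning of burst counting.
* **Edge pad.** The Gaussian kernel is acausal: the steepest rise of a
  burst's density sits up to one $\sigma$ *before* the burst's first spike,
  so the onset peak of a response beginning exactly at stimulus onset falls
  just outside the window. The peak search therefore extends
  `edge_pad = sigma` before the window's left edge. Without it a perfectly
  regular five-burst train scores four.

Derivative peaks closer than $\sigma$ are *not* merged; merging is a
documented non-feature so that the metric remains a pure local-maximum
count.

**Frequency change.** `frequency_change()` is the mean rate during the
first 5 s of stimulation minus the mean over the 5 s before it, the summary
used for graded photostimulation.

## Unconventional spikes

`detect_us()` scans consecutive spike triplets $(s_i, s_{i+1}, s_{i+2})$
left to right and emits the pair $(s_i, s_{i+1})$ when the first
interspike interval is shorter than `isi1_max` and the second longer than
`isi2_min`. The standard definition is 9/20 ms; the blue-light redefinition
relaxes the first bound to 15 ms. Both comparisons are strict, matching the
"less than"/"longer than" wording. The scan rule — a spike consumed by a US
pair is not reused as the head of the next triplet, though the triplet's
third spike may head one — is our determinism choice where the source is
silent; `mode = "all"` disables consumption for sensitivity analyses, and
the test suite pins both modes to an independent scan oracle on a thousand
random trains. USs are counted within the stimulation window by default
because spontaneous activity essentially never meets the definition.

`min_isi_comparison()` contrasts the shortest US interval with the shortest
ordinary interval of the same trial, and `us_parameter_sweep()` maps
Spearman correlations between per-trial US counts and calcium responses
over a grid of candidate definitions, flagging degenerate cells where the
count is constant.

## FRET ratio pipeline

`build_mask()` reproduces the arbor segmentation: multiply the CFP and YFP
series pixel-wise, project the product onto the time axis, equalize the
background, weight connected components, and binarize. "Morphology filter"
is under-specified in the source; we implement background equalization as
subtraction of a morphological opening with a large disc (a rolling-ball
style estimate, radius `equalize_radius` = 9 px by default — larger than a
dendrite's width), component weighting as area-opening (components smaller
than `min_area` = 5 px are dropped), and binarization by Otsu's threshold,
which is parameter-free and appropriate for the strongly bimodal product
projection.

`extract_ratio_trace()` splits a rectangular ROI into signal (ROI ∩ mask)
and background (ROI \ mask) pixels, subtracts the per-frame mean background
of each channel from its mean signal, and forms
$R = (\mathrm{YFP} - \mathrm{YFP}_{bg}) / (\mathrm{CFP} - \mathrm{CFP}_{bg})$.
The ratio orientation YFP/CFP (calcium up ⇒ ratio up) is the TN-XXL
convention; the baseline $R_0$ is the mean over the 1 s preceding stimulus
onset (the baseline length is our choice; the source does not state one).
Frames whose background-subtracted CFP is non-positive are flagged rather
than propagated. Multiplying both channels by a common factor leaves the
trace unchanged, which the tests assert.

`dr_peak()` averages the percent ratio change over 400–700 ms after
stimulus cessation — the representative value of a trial — and
`classify_transient()` applies the strict >10 % rule. The same window is
used for whole-mount and fillet recordings; it is configurable where a
study design requires otherwise. `occurrence_rate()` summarises
classifications with the exact (Clopper–Pearson) binomial interval.
`bleach_baseline()` fits $I(t) = c + a e^{-kt}$ to frames outside
irradiation windows (Levenberg–Marquardt), so stimulus-evoked dips do not
bias the photobleaching estimate; residuals from the fitted curve quantify
attenuation and recovery.

## Thermometry

The electrical resistance of a saline-filled microelectrode follows an
Arrhenius law in temperature, so $1/T_K$ is linear in $\ln R$.
`fit_arrhenius()` fits that line by least squares (kelvin internally,
Celsius at every interface) and `resistance_to_temperature()` inverts it,
warning on extrapolation beyond the calibrated resistance range. The log
base is immaterial — a base change rescales the slope — so natural log is
used. `power_to_temperature()` is the focal heating line: ambient 25 °C
plus 0.6 °C per mW of laser output, placing a 30 mW stimulus at 43 °C.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, tested code; their defaults are the study
conditions.

* `simulate_spike_train()` draws an inhomogeneous Poisson train whose rate
  steps between baseline and evoked values according to the protocol
  (on-phases only, for pulsed light), thinned by a dead time
  (`refractory`, default 2 ms) with rate compensation
  $\lambda' = \lambda/(1 - \lambda\tau)$ so realized rates still converge
  to nominal ones. US triplets are *injected by replacement* in a local
  window — not superposed — so the interspike pattern is guaranteed, each
  followed by a hard silent pause (`pause_duration`, default 150 ms; no
  published distribution exists, so this is a labelled free parameter). The
  injected first interval (5 ms) deliberately violates the ordinary
  refractory floor: that is exactly what makes the pair unconventional. An
  optional post-pause rate depression exists but is off by default, since
  the source observes the phenomenon without modelling it.
* `simulate_voltage_trace()` superposes a biphasic template at each spike
  time with Gaussian noise, carrying ground-truth peak times for the
  detector. `bandpass_filter()` mirrors the acquisition chain: first-order
  RC high-pass at 100 Hz cascaded with an 8-pole Butterworth low-pass at
  2 kHz, causal by default (a `zero_phase` flag gives offline-style
  filtering). `detect_spikes()` timestamps each threshold crossing at the
  local extremum within 1 ms and enforces a 2 ms refractory window so a
  biphasic waveform is counted once; polarity is a flag because the
  acquisition convention is not recorded.
* `simulate_fret_stack()` builds paired CFP/YFP stacks: a random branched
  arbor, anti-correlated channel deflections
  ($\mathrm{YFP} \propto \sqrt{1 + \Delta R/100}$, CFP its inverse, so the
  amplitude is parameterised on the ratio, not the channels), simultaneous
  onset across the arbor, monoexponential decay (slower in the soma),
  common-mode photobleaching, a background pedestal under all pixels, and
  Gaussian noise. `transient_amplitude` is defined as the ground-truth
  *representative* ratio change — the 400–700 ms post-cessation window
  average — so recovery tests compare like with like.
* `simulate_coupled_trial()` couples the ratio amplitude linearly to the
  train's realized US count under the 9/20 ms definition (embedded
  triplets plus any chance Poisson triplets), plus optional noise. Coupling
  to the realized rather than the embedded count keeps the zero-noise
  Spearman correlation exactly 1, the contract correlation-recovery tests
  rely on.
* `simulate_calibration_data()` draws resistance–temperature pairs on the
  Arrhenius line with noise on the $1/T_K$ scale, spanning 20–55 °C.

What the generators do *not* emulate: biophysical channel gating (firing
statistics are phenomenological), spike-waveform diversity, optical blur
and motion, soma/neurite brightness heterogeneity, or correlated imaging
noise. Passing tests therefore demonstrate the correctness of the analysis
chain on data with the assumed statistical structure, not robustness to
every artefact of real recordings.

## Numerical choices and degenerate inputs

Density and derivative grids default to 1 ms and 0.1 ms; the peak search
uses strict/non-strict inequality on the two flanks of a maximum and
collapses exact plateaus to their first sample. Empty trains yield zero
rates, an error for `time_to_max()` (undefined), and empty US lists. A
trial without USs makes the within-US minimum `NA` with a warning.
All-zero or uniform stacks are rejected by `build_mask()` with specific
errors; ROIs without mask overlap error; background-free ROIs fall back to
no subtraction with a warning. Constant vectors make the Spearman
correlation `NA` and are flagged. Non-convergent bleach fits return the
linear trend, flagged. A master seed fans out to per-trial child seeds as
`seed + 101 * i`, so runs are reproducible bit for bit and stages are not
coupled through the random stream.

## Problem sizes used by the validation suite

The shipped tests run the US-detector oracle on 1000 random trains, the
max-rate oracle on 100, amplitude recovery on 40 × 40 px × 70-frame stacks
over 20 seeds per amplitude (5, 10, 15, 30 %) at zero and stated noise,
interval coverage on 10⁴ binomial draws, and the intermittent-activation
metric on 90 simulated 9-train experiments. These sizes were chosen so the
Monte-Carlo error of each check is small against its acceptance band.

## Known limitations

* The Poisson-with-dead-time firing model reproduces rates and the
  burst/pause architecture, not full ISI distributions; per-pulse spike
  counts are more variable than in strongly driven real neurons, which is
  visible as non-zero variance of the total peak number under pulsed
  drive.
* The mask pipeline assumes co-registered, motion-free channels (trials
  with movement are excluded, not corrected, in the source workflow).
* `us_parameter_sweep()` reports the full correlation map and does not
  arbitrate an optimal definition.
* The spatial temperature profile is treated as repeated application of
  the R–T transform; no heat-diffusion model is included.
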