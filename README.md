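# burstpause

Quantitative analysis of **burst-and-pause firing** and **dendritic
calcium transients** in *Drosophila* larval class IV nociceptive neurons —
the measurement chain that connects focal heat or optogenetic stimulation,
extracellular spike trains, and ratiometric (FRET) calcium imaging.

Class IV dendritic-arborization neurons respond to noxious heat (above
~43 °C) with high-frequency firing interrupted by silent pauses, and with
calcium transients that invade the entire dendritic arbor. Two derived
quantities summarise this behaviour:

* **Unconventional spikes (US).** From three sequential spikes
  $(s_i, s_{i+1}, s_{i+2})$, the pair $(s_i, s_{i+1})$ is a US when
  ISI₁ < 9 ms and ISI₂ > 20 ms (the blue-light redefinition relaxes the
  first bound to 15 ms). USs mark the burst-then-pause signature.
* **Total peak number.** Estimate the firing rate by Gaussian-kernel spike
  density (σ = 25 ms), differentiate it (0.1 ms grid), and count the local
  maxima inside the stimulation window that exceed 0.5 × the primal
  (response-onset) peak. Each accepted peak is one discrete rise of the
  firing rate — one burst.

Around these the package provides: sliding rectangular-window firing rates
(Δt = 400 ms), maximum firing rate and time-to-max latency, stimulus-locked
frequency change, voltage-trace conditioning (RC 100 Hz high-pass +
8-pole Butterworth 2 kHz low-pass) and threshold spike detection, waveform
alignment/averaging, the FRET pipeline (binary-mask arbor segmentation,
ROI background subtraction, ΔR/R₀ traces, the 400–700 ms post-stimulus
ΔR_peak, the >10 % transient rule, Clopper–Pearson occurrence rates,
photobleach-baseline fits), electrode-resistance Arrhenius thermometry
(1/T_K = a + b·ln R) with the IR-laser power→temperature line
(25 °C + 0.6 °C/mW), the supporting statistics (Spearman, Wilcoxon,
Fisher, Bonferroni, stride speed), and synthetic-data generators with
ground truth for every stage.

## Worked example

Simulate one heat-stimulation trial (IR protocol: onset 1 s, duration 1 s,
30 mW) with three embedded USs, then run the metrics:

```r
library(burstpause)

prot  <- ir_protocol(onset = 1, duration = 1, power = 30)
spec  <- train_spec(baseline_rate = 2, evoked_rate = 60, us_events = 3,
                    seed = 42)
train <- simulate_spike_train(spec, prot)
train
#> <spike_train> trial1: 46 spikes over [0.000, 3.000] s
#>   stimulus: IR at 1.000 s for 1.000 s

max_firing_rate(train)          # Hz, best 400 ms window
#> [1] 55
detect_us(train)                # US pairs inside the stimulation window
#>   first_spike second_spike  isi1_ms   isi2_ms trial_id
#> 1    1.003948     1.007334 3.385808  30.09689   trial1
#> 2    1.037431     1.042989 5.557763  39.44876   trial1
#> 3    1.140833     1.145833 5.000000 187.59388   trial1
#> ...
total_peak_number(train)
#> <derivative_peaks> 8 peak(s) above 429.8 Hz/s in [1.00, 2.00] s
power_to_temperature(30)        # focal temperature at 30 mW
#> [1] 43
```

The 55 Hz maximum rate is the evoked firing seen through the 400 ms
window; the detected USs include the three embedded pairs (ISI₁ = 5 ms,
followed by their 150 ms pauses) plus chance triplets of the Poisson
background; and 8 derivative peaks reflect the burst structure that the
pauses carve into the train.

The same machinery runs as one reproducible pipeline over a set of
coupled spike-train/calcium trials:

```r
run <- run_pipeline(run_config(seed = 1, n_trials = 12, noise = 2))
run
#> <pipeline_run> 12 trials (seed 1)
#>   Spearman rho(US count, dR_peak) = 0.964 (p = 4.24e-07)
#>   transient occurrence 100.0% [73.5, 100.0]
#>   mean max rate 59.6 Hz, mean total peak number 5.58
```

i.e. the per-trial US count ranks the calcium response almost perfectly at
this coupling noise, every trial crosses the 10 % transient threshold
(exact binomial CI 73.5–100 %), and the manifest in `run$manifest` is
sufficient to re-run the analysis bit for bit.

## Layout

* `R/` — implementation (simulation, ephys conditioning, firing metrics,
  US detection, FRET pipeline, thermometry, statistics, pipeline driver,
  CSV/TIFF/JSON/YAML I/O)
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles in `helper-oracles.R`
* `vignettes/burst-and-pause-analysis.Rmd` — the methods vignette: model
  assumptions, parameter conventions, numerical choices, limitations
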