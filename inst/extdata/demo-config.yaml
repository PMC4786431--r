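# Demo pipeline configuration: 12 coupled heat-stimulation trials with the
# conventional analysis parameters.
seed: 1
n_trials: 12
max_us: 4
gain: 5
noise: 2
rate_dt: 400
density_sigma: 25
us_isi1_max: 9
us_isi2_min: 20
dr_window: [0.4, 0.7]
transient_threshold: 10
protocol:
  kind: IR
  onset: 1
  duration: 1
  power: 30
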