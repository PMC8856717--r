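# Smoke configuration: a short, seizure-dense recording with small forests,
# sized so a full pipeline run finishes in well under two minutes.
seed: 1
output_dir: swdpredict-smoke-out
synthetic:
  preset: gaers
  fs: 100
  duration_s: 1200
  base_swd_rate_per_h: 60
  diurnal_mod_amp: 0
  swd_duration_s: [8, 15]
  sites: [S1_L4, S1_L5, S1_L6]
detector:
  combination: [S1_L4, S1_L5, S1_L6]
  stride_s: 0.02
  target_sensitivity_pct: 90
classifier:
  mode: undersample
  n_forests: 5
  n_trees: 20
surrogate:
  n_randomizations: 20
  n_trees: 20
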