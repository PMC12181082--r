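schema_version: '1.0'
simulate: yes
study:
  n_annotators: 9
  n_cases: 10
  methods:
  - manual
  - dl
  seed: 1
shape:
  grid_shape:
  - 40
  - 56
  - 56
  spacing_mm:
  - 2.0
  - 1.0
  - 1.0
  base_radius_range_mm:
  - 12.0
  - 16.0
  irregularity: 0.25
  lobe_count: 3
panel:
  sigma_inter_mm: 2.8
  sigma_intra_mm: 1.35
  dl_bias_scale: 0.78
  focal: ~
logs:
  manual:
    session_duration_s: 1320.0
    active_fraction: 0.33
    observation_scale_s: 4.4
    interruption_rate: 1.0
    tool_mix:
      lasso: 0.6
      brush: 0.2
      eraser: 0.15
      scissors: 0.05
  dl:
    session_duration_s: 1219.812
    active_fraction: 0.2749702
    observation_scale_s: 4.4
    interruption_rate: 1.0
    tool_mix:
      lasso: 0.55
      brush: 0.2
      eraser: 0.2
      scissors: 0.05
staple:
  threshold: 0.5
  tol: 1.0e-07
  max_iter: 200
  roi_margin: 10.0
  scope: per_method
apl:
  tolerance_mm: 2.0
deviation:
  levels:
  - 0.1
  - 0.3
  - 0.5
  - 0.7
  - 0.9
  align: no
time:
  break_threshold_s: 85.0
  bin_edges_s:
  - 0.0
  - 1.0
  - 10.0
  - 50.0
  - 85.0
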