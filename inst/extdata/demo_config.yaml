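# Demonstration run: synthetic inputs small enough to finish in about a
# minute while exercising every pipeline stage.
synthetic:
  grid: {n_rows: 48, n_cols: 48, lon_min: -6, lat_min: 20, cell_size: 0.5}
  layers:
    - {name: bio01, kind: temperature}
    - {name: bio05, kind: temperature}
    - {name: bio12, kind: precipitation}
    - {name: bio14, kind: precipitation}
    - {name: elev, kind: terrain}
  corr_length: 6
  K: 4
  prevalence_skew: 2
  n_points: 600
  n_clusters: 12
  label_noise: 0.1
seeds: {data: 42, folds: 43, model: 44}
block_size_km: 100
k: 5
repeats: 1
run_cv: true
mov_threshold: 50
filter_mode: both
scenarios:
  - {tag: rcp26_2061_2080, temperature_shift: 1.0, precipitation_scale: 0.95}
  - {tag: rcp85_2061_2080, temperature_shift: 4.0, precipitation_scale: 0.85}
out_dir: biomeshift_demo_out
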