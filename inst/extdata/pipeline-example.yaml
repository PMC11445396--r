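# Example configuration for run_pipeline(): synthetic preset end to end.
# For real data replace `synthetic:` with
#   spatial:     {counts: spatial_counts.tsv, coords: coordinates.csv}
#   single_cell: {counts: sc_counts.mtx}
out_dir: pipeline-out
synthetic:
  preset: small
  seed: 1
covet:
  k: 8
  log1p: true
envi:
  latent_dim: 16
  hidden_layers: 2
  hidden_width: 64
  train_steps: 400
  batch_size: 128
  seed: 1
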