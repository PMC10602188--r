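# Demonstration run configuration for run_pipeline() / run_pipeline.R.
# Mirrors generator_config() and split_protocol() fields.
generator:
  seed: 7
  n_genes: 40
  variants_per_gene: [5, 30]
protocol:
  repeats: 3
  c_grid: [0.01, 0.1, 1.0, 10.0, 100.0]
stages: [curate, evaluate, classify, saturate]
resampling_repeats: 100
min_group: 50
saturation:
  n_proteins: 5
  min_len: 100
  max_len: 300
  cutoff: -1.1
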