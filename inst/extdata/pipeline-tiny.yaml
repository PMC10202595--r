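# A small complete SAG-RAD pipeline configuration: three demes of three
# single cells each, 200 RAD loci, moderate amplification bias.
seed: 1
sim:
  n_populations: 3
  n_individuals_per_pop: 3
  n_loci: 200
  reads_per_sample: 5000
  het_rate: 0.05
  divergence: 0.02
  mda_sigma: 0.8
  dropout_prob: 0.2
  contamination_frac: 0.05
  pcr_dup_rate: 0.1
  seq_error_rate: 0.001
qc:
  min_loci: 50
coancestry:
  k: 3
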