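# Demo run: small seeded synthetic study, all stages.
seed: 7
simulate:
  n_samples_per_group:
    clay_loam: 20
    sandy: 40
  n_taxa: 60
  sequencing_depth: 5000
  dispersion: 0.5
diversity:
  n_perm: 199
stability:
  n_iterations: 60
  sample_n_iterations: 20
plspm:
  n_boot: 100
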