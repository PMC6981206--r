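# Minimal synthetic-mode pipeline configuration.
simulation:
  n_baits: 12
  preys_per_bait: 25
  seed: 42
thresholds:
  p_max: 0.05
  sig_a_max: 0.05
protein_tables:
  n_de: 100
  n_dp: 80
  n_universe: 1500
r_lo: 150
r_hi: 400
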