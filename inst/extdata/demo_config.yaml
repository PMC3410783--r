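# Demo run: synthetic planted study at the emulated design (2 RA / 3 O2
# replicates, 2000 probes, 300 miRNAs) with default thresholds.
seed: 42
synthetic:
  n_probes: 2000
  n_mrna_de: 50
  mrna_effect: 2.5
  mrna_sd: 0.25
  n_mirnas: 300
  n_mirna_de: 8
  mirna_effect: 3
  mirna_sd: 0.25
  n_shared_bc: 10
  ceiling_fraction: 0.2
thresholds:
  mrna_fc: 2
  mirna_fc: 4
  fdr: 0.05
  min_log2: 5
  min_fraction: 0.5
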