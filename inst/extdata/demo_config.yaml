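# Demo configuration for `run_all()` / `mosaicx run`.
# Desk-scale sizes; all seeds derive from `seed`.
seed: 1
sim:
  cells_per_sample: 50
  n_genes: 600
  mean_locus_umis: 3
  module_spec:
    size: [30, 30, 30]
    cor: [0.6, 0.6, 0.6]
parser:
  min_identity: 0.9
  min_evidence: 1
  majority_threshold: 0.8
network:
  pooling_size: 10
  min_module_size: 15
deg:
  fdr: 0.05
  min_cells: 10
human:
  cells_per_sample: 40
  n_genes: 600
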