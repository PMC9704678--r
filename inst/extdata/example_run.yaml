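# desk-scale synthetic pipeline configuration
foci: synthetic
expression: synthetic
atlas: synthetic
genes: [MECP2, SHANK1, SHANK2, SHANK3, NLGN3, NLGN4X, NRXN1, CNTNAP2]
seed: 1
n_experiments: 40
subjects_range: [10, 30]
k_networks: 9
grid:
  voxel_mm: 4
ale:
  fwhm_mm: 10
  alpha: 0.05
  min_cluster_mm3: 150
  n_null: 10000
perm:
  n_perm: 10000
  ci: 0.95
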