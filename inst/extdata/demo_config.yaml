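# Demo configuration for the synthetic end-to-end pipeline.
# Stage parameters keep their standard defaults (peak q 0.01, blacklist
# shared-by-5, consensus pad 100 / min overlap 2, top-3000 correlation
# filter, alpha 0.05, 150 bp motif window, promoter +/- 1 kb).
params:
  seed: 42
  target_permutations: 200
synthetic:
  n_chroms: 2
  chrom_length: 300000
  n_genes: 300
  n_peaks_shared: 150
  n_peaks_hetero_specific: 80
  n_peaks_homo_specific: 80
  peak_width: 400
  nb_mean: 100
  nb_dispersion: 0.1
  fold_change: 4
  n_replicates: 2
  n_controls: 6
  n_artifact_regions: 5
  frac_peaks_near_tss: 0.4
  deg_target_fraction: 0.8
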