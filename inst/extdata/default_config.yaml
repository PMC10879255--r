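# Default pipeline configuration: synthetic cohort with planted 3-group
# structure, consensus k-means over k = 2-6 (H = 100 resamples, p = 0.8),
# gap statistic with B = 50 uniform references, top 5000 variance-ranked
# CpG features.
input: synthetic
seed: 7
out_dir: methgroups_results
synthetic: {}
clustering:
  k_range: [2, 6]
  H: 100
  p: 0.8
  B: 50
  n_top: 5000
hmr:
  tau: 0.3
  max_gap: 500
  min_cpgs: 4
  min_cov: 5
cnv:
  bin_size: 500000
  t_threshold: 4
  min_bins: 5
  call_cutoff: 0.3
de:
  lfc_threshold: 1
  p_threshold: 0.05
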