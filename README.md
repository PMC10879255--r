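# methgroups

Unsupervised discovery and characterization of **DNA methylation groups**
in tumor whole-genome bisulfite sequencing (WGBS) cohorts, written for
analysts who need the full multi-stage workflow as tested, composable R
functions: molecular-group discovery from CpG beta values, hypomethylated
region (HMR) and copy-number (CNV) characterization, paired one-vs-rest
differential expression with gene-set enrichment, and cohort-level group
comparisons. A synthetic cohort generator plants known structure so every
stage can be validated against ground truth.

## The method

Let $B$ be the samples × CpG beta-value matrix restricted to the 5,000
most variable, well-covered sites. `meth_groups()` decides the number of
groups $k$ from two independent lines of evidence and assigns samples:

* **Consensus k-means** (k = 2–6, H = 100 subsamples at fraction p = 0.8):
  consensus matrix $C_k(i,j)$ = fraction of co-sampled runs in which
  samples $i, j$ co-cluster; stability is summarized by the area $A(k)$
  under the CDF of the consensus entries and the relative delta-area
  $\Delta(k) = (A(k)-A(k-1))/A(k-1)$, whose elbow marks the last $k$ that
  still adds stability.
* **Gap statistic** (B = 50 Monte-Carlo references, uniform over observed
  feature ranges): $\mathrm{Gap}(k) = \tfrac1B\sum_b \log W^*_{kb} -
  \log W_k$ with $W_k = \sum_r \tfrac{1}{2n_r}\sum_{i,j \in C_r} d^2(i,j)$
  (= within-cluster sum of squares) and reference standard error $s_k$.
  The classical one-SE selection is reported; the primary decision uses a
  self-calibrating jump rule that is robust in high-dimensional feature
  panels (see the methods vignette for the analysis behind this).

Ward hierarchical clustering and PCA/UMAP/t-SNE embeddings corroborate the
partition. Downstream: HMRs are maximal runs of low-beta CpGs (beta < 0.3,
gap ≤ 500 bp, ≥ 4 CpGs) annotated against CpG islands, their ±2 kb shores
and the next ±2 kb shelves; CNVs come from 500 kb coverage bins, median
normalization and recursive Welch-t binary segmentation; differential
expression is a per-gene Welch t on log2(TPM+1) with the volcano
convention |log2FC| > 1 and p < 0.05; enrichment is a hypergeometric
over-representation test; cohort contrasts use the pooled-variance
Student's t.

## Worked example

```r
library(methgroups)
sim <- generate_cohort(synthetic_config(), seed = 7)   # 30 samples, 3 groups
fit <- meth_groups(sim$cohort, seed = 7)
fit
#> Methylation group discovery: 30 samples, 5000 CpG features
#>   selected k = 3 (gap statistic; delta-area k = 3, concordant)
#>   group sizes: 1: 12, 2: 10, 3: 8
summary(fit)
#> Selected number of methylation groups: 3
#>   gap statistic: k = 3 (unrestricted k = 5)
#>   consensus delta-area elbow: k = 3 (threshold 0.10)
#>
#> Per-k diagnostics (consensus CDF area/delta, dispersion, gap):
#>  k   area   delta       W     gap        s
#>  1     NA      NA 21224.5 -0.6861 0.002615
#>  2 0.4598 0.45977  7952.1  0.2582 0.002691
#>  3 0.6805 0.48000   458.0  3.0743 0.002595
#>  4 0.7083 0.04096   438.9  3.0774 0.002639
#>  5 0.7428 0.04864   420.2  3.0801 0.002699
#>  6 0.7709 0.03786   402.3  3.0809 0.002711
adjusted_rand_index(fit$labels, sim$truth$labels)
#> [1] 1
```

Reading the output: the within-cluster dispersion `W` collapses from ~7,950
to ~458 when a third group is allowed and barely improves after that; the
gap jumps by 2.8 into k = 3 and then gains < 0.01 per extra k; the
delta-area drops from 0.48 to 0.04 past k = 3. Both criteria agree on three
methylation groups, and the final assignment reproduces the planted labels
exactly (adjusted Rand index 1).

The same analysis runs end-to-end from files (coverage tables, BED tracks,
counts, GMT, metadata) with a YAML config:

```r
run_pipeline(system.file("extdata", "default_config.yaml",
                         package = "methgroups"),
             out_dir = "results", seed = 7)
```

or from a shell via `inst/cli/methgroup.R` with per-stage subcommands
(`simulate`, `cluster`, `hmr`, `cnv`, `de`, `enrich`, `stats`, `report`).

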