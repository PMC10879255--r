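---
title: "Discovering DNA methylation groups in tumor WGBS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering DNA methylation groups in tumor WGBS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methgroups)
```

## The analysis problem

Unsupervised analyses of tumor DNA methylation repeatedly find that a tumor
entity decomposes into a small number of molecular groups with distinct
biology. Establishing such groups from whole-genome bisulfite sequencing
(WGBS) is a multi-stage analysis: per-CpG methylation fractions (beta
values) are summarized into a feature matrix; the number of groups is
chosen from stability and dispersion evidence; samples are assigned to
groups; and the groups are characterized genomically (hypomethylated
regions, copy-number burden), transcriptionally (one-vs-rest differential
expression with gene-set enrichment) and clinically (mitotic index, WHO
grade). This package implements that pipeline as a set of tested,
composable operations around one central fitting function, `meth_groups()`,
and pairs it with a synthetic cohort generator that plants known group
structure so that every stage can be validated against a truth ledger.

## The model behind `meth_groups()`

The feature matrix contains, for each of the $n$ samples, the beta values
of the `n_top` CpG sites (default 5,000) with the highest across-sample
variance; sites below the coverage floor in any sample are excluded first.
Variance ranking is the field's default when no supervised criterion is
available; ties are broken by genomic order so the selection is
deterministic.

Three lines of evidence about the number of groups $k$ are computed:

**Consensus k-means stability.** For each $k$ in the candidate range
(default $2\ldots6$), $H = 100$ subsamples of a fraction $p = 0.8$ of the
samples are clustered with k-means (Lloyd's algorithm, squared-Euclidean
objective, best of 20 restarts, empty clusters repaired by splitting off
the farthest point). The consensus matrix entry $C_k(i,j)$ is the fraction
of co-sampled runs in which $i$ and $j$ co-clustered. Stable structure
pushes the entries toward $\{0, 1\}$; the empirical CDF of the
upper-triangle entries and its area $A(k)$ quantify this. The relative
delta-area $\Delta(k) = (A(k) - A(k-1))/A(k-1)$ (with $\Delta$ at the
smallest $k$ equal to $A$ itself) has an elbow at the last $k$ that still
adds stability; the elbow is taken as the largest $k \ge 3$ with
$\Delta(k)$ above 0.1.

Internally, all subsampled k-means runs operate on the Gram matrix of the
feature matrix: squared distances to centroids are linear functions of
Gram entries, so a subsample only indexes into one precomputed $n \times n$
matrix. This makes $H \cdot |k\_range| \cdot 20$ restarts essentially free
at cohort sizes, without changing the algorithm.

**Gap statistic.** The within-cluster dispersion
$W_k = \sum_r \frac{1}{2 n_r} \sum_{i,j \in C_r} d^2(i,j)$ (identical to
the within-cluster sum of squares; the identity is asserted in the tests)
is compared against $B = 50$ Monte-Carlo reference datasets with each
feature drawn uniformly over its observed range:
$\mathrm{Gap}(k) = \frac1B \sum_b \log W^*_{kb} - \log W_k$, with
$s_k = \mathrm{sd}_b(\log W^*_{kb})\sqrt{1 + 1/B}$. `gap_statistic()`
reports the classical one-standard-error selection (smallest $k$ with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$).

**Hierarchical clustering and embedding.** Ward linkage on Euclidean
distances (Ward matches the k-means variance objective) provides a
corroborating dendrogram and the leaf order for heatmaps; `embed_samples()`
provides PCA (thin SVD of the centered matrix, implemented here) and
delegates UMAP/t-SNE to uwot/Rtsne behind the same contract.

### Why the final k-selection does not use the raw one-SE rule

The one-SE rule presumes that $s_k$ captures the uncertainty of gap
differences. With thousands of near-independent features, $s_k$ shrinks
like $1/\sqrt{np}$ (about 0.0025 at $n = 30$, $p = 5000$), while the gap
increments beyond the true $k$ retain a small systematic positive bias
(order 0.003–0.01): the cluster optimizer on the real data exploits
per-sample noise heterogeneity slightly better than on the homoscedastic
uniform reference, and variance-ranked feature panels amplify this. The
raw rule then chases sub-percent gap gains into ever larger $k$ — we
verified the identical behavior with an independent implementation
(`cluster::clusGap`) on the same matrices, so this is a property of the
procedure, not of our code.

`select_k()` therefore makes the primary decision with a self-calibrating
*jump rule* (`gap_k_robust()`): the curve's intrinsic creep is estimated
as the median gap increment, and a candidate $k$ is accepted only when the
increment into it exceeds that baseline by more than twice the reference
standard error. The selected $k$ is the largest accepted jump; with no
accepted jump the smallest $k$ in range is returned (no evidence of added
structure). The rule is scale-free, needs no tuned constant beyond the
conventional 2-SE margin, reduces to sensible behavior in low dimensions
(where it agrees with the classical rule on well-separated data), and
prefers $k = 1$ on structureless cohorts where the raw rule never does.
The classical selections (restricted and unrestricted) are reported in the
selection object and the diagnostics table, and the delta-area elbow
corroborates the decision with a concordance flag. Discordance is logged,
never fatal.

Final labels come from k-means on the full feature matrix (best of 50
restarts), with groups renumbered by descending size so group 1 is always
the largest.

## Methylome characterization

**Context track.** CpG islands come in as BED intervals; shores are their
±2 kb flanks and shelves the next ±2 kb, with overlaps resolved by
precedence (island > shore > shelf) and everything else open sea. The
track partitions each chromosome exactly; an IRanges-based reconstruction
serves as an independent oracle in the tests.

**HMR caller.** A CpG site is hypomethylated when its beta value is below
`tau` (default 0.3) at coverage at least `min_cov` (default 5). Maximal
runs of hypomethylated sites with successive positions at most `max_gap`
(default 500 bp) apart form candidate regions; those with at least
`min_cpgs` (default 4) sites are reported with their unweighted mean beta.
This transparent threshold–merge segmenter was chosen over HMM-based
callers for testability; its parameters are declared conventions. Sites
below the coverage floor are invisible to the caller (they neither qualify
nor break a run unless the remaining gap exceeds `max_gap`). Context is
assigned by maximal base overlap (ties to the higher-precedence class),
and the summary also reports an any-overlap island-or-shore fraction for
comparison. Genomic elements use any-overlap precedence promoter > exon >
intron > intergenic with the promoter at TSS −2,000/+500 bp, a common
convention.

**CNV segmentation.** Coverage (all reads, including methylation-masked
sites) is summed in 500 kb bins, normalized within each sample by its
median bin coverage and across the cohort by the per-bin median of those
ratios, yielding a log2 ratio per bin. Chromosomes are segmented by
recursive binary splitting: the split maximizing Welch's $|t|$ between the
flanking bin means is accepted when $|t| > 4$ with at least `min_bins = 5`
bins per side. Segments with mean log2 ratio beyond ±0.3 are called
gain/loss, and `genome_fraction_cnv()` reports the affected genome
fraction. Two caveats are documented rather than hidden: GC-content
correction is omitted (the synthetic data has no GC structure), and the
`min_bins` constraint can leave a short neutral flank merged into a call
whose true boundary is closer than 5 bins to another boundary, diluting
that segment's mean — the planted-recovery tests show both the clean
single-carrier geometry and this cohort-level dilution.

## Expression and cohort statistics

Counts are TPM-normalized from gene lengths. One-vs-rest differential
expression works on $\log_2(\mathrm{TPM}+1)$: Welch t per gene, log2 fold
change as the difference of group means, Benjamini–Hochberg q alongside,
and the significance flag uses the volcano convention $|\mathrm{log2FC}| >
1$ and raw $p < 0.05$ (the corrected q is reported but deliberately not
used for the flag, mirroring the convention stated with the thresholds).
Gene-set enrichment is a one-sided hypergeometric over-representation test
over the count-matrix universe, replacing any web-service dependency; BH
across sets.

Cohort comparisons use the pooled-variance two-sample Student's t — also,
deliberately, for the binary high-grade indicator and the group-vs-rest
design, reproducing the analysis style this pipeline emulates; a Fisher
exact test would be the usual categorical alternative, and the caveat is
stated here rather than silently "fixed".

## The synthetic cohort generator

`generate_cohort()` emulates the study design the analysis assumes: 30
samples in three latent groups at proportions 0.40/0.35/0.25 (sizes
12/10/8 by largest-remainder rounding; ties go to the group with the
smaller integer part), a 2 × 10 Mb genome with 20,000 CpGs and 200 CpG
islands of 1 kb on a regular grid. Baseline methylation is high in open
sea (Beta(8,2)) and low in islands (Beta(1.5,8)), drawn once per site and
shared across samples — methylation baselines are locus properties, so
within-group variation comes from binomial sampling at Poisson depth
(mean 30). Each group owns planted hypomethylated blocks (150 per group;
300 for the HMR-enriched group 2) of 8–20 consecutive CpGs at Beta(1,9).
Blocks never overlap across groups.

Sixty percent of CpGs lie in island ±4 kb neighborhoods; these are placed
on a jittered regular grid (spacing ≈ 150 bp), the rest uniformly. The
grid guarantees that a planted block is a dense run recoverable under the
HMR caller's 500 bp gap rule; fully uniform placement would space open-sea
CpGs ~2.3 kb apart and make planted blocks unrecoverable by construction,
which would say nothing about the caller. This is the one place where the
generator is deliberately friendlier than real methylomes, and it is why
HMR recovery rates here should not be read as real-data sensitivity.

Each group carries one planted CNV segment (1.5× gains, one 0.5× loss)
that scales sequencing depth; expression counts are negative binomial
(dispersion 0.1) around a log-normal baseline with 200 planted DE genes
per group (half up, half down at |log2FC| = 2). Planted DE genes sit at
fixed gene indices and the proliferation-marker-like genes (`MKI67L`,
`TOP2AL`, `FOXM1L`, log2FC 2.5 in group 2) at fixed positions, so the
packaged hallmark-like GMT fixture can reference them; methylation block
positions remain seed-dependent. Mitotic index is Poisson with mean 6 in
group 2 and 1 elsewhere; the probability of high WHO grade (2–3) is 0.8
in group 2 versus 0.15.

One master seed drives everything; per-stage child seeds are derived by
fixed offsets so that re-running a single stage reproduces the monolithic
run. What the generator does **not** emulate: read-level errors, sequence
context and GC structure, strand-resolved CpGs, correlated (regional)
biological variation within groups, batch effects, and sample-level global
methylation shifts. Passing tests on this cohort demonstrate correctness
of the operations under the planted model, not performance on real
tumors.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package;
  readers/writers convert at the boundary only (`bismark` 1-based and
  `bedgraph` 0-based dialects both accepted).
* Beta values are recomputed from counts on input, so they are exact
  rather than limited to the printed percentage precision; writers emit
  percentages at fixed precision and counts carry the full information,
  making round trips exact.
* k-means restarts draw k distinct data rows as initial centers;
  `max.col(..., ties.method = "first")` keeps assignments deterministic.
* Zero-variance genes give log2FC 0 and p 1; zero pooled variance with
  unequal means gives p 0 with a warning; empty enrichment queries give
  p 1; an empty HMR table yields an empty summary, not an error.
* Consensus pairs never co-sampled (vanishing probability at the
  defaults) are set to the neutral value 0.5 with a warning.
* Coverage bins with zero cohort median are masked with a warning;
  coverage is floored at 0.5 reads per bin so log ratios stay finite.
* Result writers format floats at fixed precision, so re-running a stage
  on identical inputs is byte-identical.

## Problem sizes used in the test suite

Unit tests run on scaled-down cohorts (12 samples, 2,400 CpGs, 1,200
genes) chosen to exercise every code path in seconds; the acceptance suite
runs the full default design (30 samples, 20,000 CpGs, consensus H = 100,
gap B = 50) across 10 master seeds, the calibration checks use 1,000 null
genes and 10,000 null t-test replicates, and the whole suite completes in
a few minutes on one CPU. These sizes are the package's own validation
design.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config()
sim <- generate_cohort(cfg, seed = 7)
fit <- meth_groups(sim$cohort, seed = 7)
summary(fit)
adjusted_rand_index(fit$labels, sim$truth$labels)
```

The same analysis runs from files via `run_pipeline()` (YAML-configured,
with per-stage subcommands in `inst/cli/methgroup.R`), writing TSV/BED
result tables, a JSON report and a Markdown report.

## Known limitations

* The HMR caller measures gaps on the hypomethylated subset; long
  stretches of covered-but-methylated sites inside `max_gap` do not break
  a run. For island-dense designs this matches intent; for sparse designs
  consider lowering `max_gap`.
* CNV boundaries are bin-quantized and constrained by `min_bins`;
  breakpoint-precise calling is out of scope.
* The DE test is a per-gene Welch t on transformed TPM, not a count-model
  GLM; with few samples per group a negative-binomial framework has more
  power.
* Group discovery assumes the groups are separable in the top-variance
  CpG panel; methylation subgroups nested within groups are not modeled.
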