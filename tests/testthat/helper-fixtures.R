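# Shared fixtures built in code.

# Gaussian point clouds at given centers (n per cloud, d dimensions).
make_clouds <- function(centers, n_per = 10, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- as.matrix(centers)
  d <- ncol(centers)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(stats::rnorm(n_per * d, mean = rep(centers[i, ], each = n_per),
                        sd = sd), n_per, d)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# A scaled-down synthetic configuration for fast unit tests (overridable
# defaults). The full-size defaults are exercised by the acceptance suite.
tiny_config <- function(...) {
  args <- list(n_samples = 12, n_cpgs = 2400, n_islands = 40,
               chrom_length_bp = 2e6,
               blocks_per_group = 20, hmr_group_blocks = 40,
               n_genes = 1200, de_genes_per_group = 60,
               cnv_segments = list(
                 data.frame(chrom = "chr1", start = 5e5, end = 1.5e6,
                            multiplier = 1.5),
                 data.frame(chrom = "chr2", start = 5e5, end = 1.5e6,
                            multiplier = 0.5),
                 data.frame(chrom = "chr2", start = 0, end = 5e5,
                            multiplier = 1.5)))
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# Build a minimal MethylationCohort directly from matrices (sites x samples).
manual_cohort <- function(chrom, start, n_meth, n_total, chrom_lengths,
                          min_coverage = 5) {
  ids <- sprintf("S%02d", seq_len(ncol(n_total)))
  dimnames(n_meth) <- dimnames(n_total) <- list(NULL, ids)
  structure(list(
    sites = data.frame(chrom = chrom, start = start, end = start + 1,
                       stringsAsFactors = FALSE),
    beta = ifelse(n_total > 0, n_meth / n_total, NA_real_),
    n_meth = n_meth, n_total = n_total, sample_ids = ids,
    chrom_lengths = chrom_lengths, min_coverage = min_coverage),
    class = "MethylationCohort")
}
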