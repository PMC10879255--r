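test_that("group apportionment uses largest remainders with the stated tie-break", {
  expect_equal(apportion_groups(30, c(0.40, 0.35, 0.25)), c(12L, 10L, 8L))
  expect_equal(apportion_groups(10, c(0.5, 0.5)), c(5L, 5L))
  expect_equal(sum(apportion_groups(29, c(0.4, 0.35, 0.25))), 29L)
  # remainder goes to the largest fractional part
  expect_equal(apportion_groups(10, c(0.56, 0.44)), c(6L, 4L))
  # exact .5/.5 tie goes to the group with the smaller integer part
  expect_equal(apportion_groups(10, c(0.55, 0.45)), c(5L, 5L))
})

test_that("default cohort has the documented shape and is seed-deterministic", {
  sim1 <- generate_methylomes(synthetic_config(), seed = 7)
  expect_equal(dim(sim1$cohort$beta), c(20000L, 30L))
  expect_equal(unname(table(sim1$truth$labels)[1:3]), c(12L, 10L, 8L),
               ignore_attr = TRUE)
  sim2 <- generate_methylomes(synthetic_config(), seed = 7)
  expect_identical(sim1$cohort$n_meth, sim2$cohort$n_meth)
  expect_identical(sim1$truth$labels, sim2$truth$labels)
  sim3 <- generate_methylomes(synthetic_config(), seed = 8)
  expect_false(identical(sim1$cohort$n_meth, sim3$cohort$n_meth))
})

test_that("planted blocks never overlap across groups", {
  sim <- generate_methylomes(tiny_config(), seed = 3)
  b <- sim$truth$blocks
  for (ch in unique(b$chrom)) {
    sub <- b[b$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
})

test_that("observed beta concentrates on the true beta at high depth", {
  # all CNV multipliers 1 (no planted segments), depth mean 10,000
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), multiplier = numeric(0))
  cfg <- tiny_config(depth_mean = 10000, n_samples = 6, n_cpgs = 600,
                     n_islands = 10, chrom_length_bp = 1e6,
                     blocks_per_group = 5, hmr_group_blocks = 10,
                     cnv_segments = list(empty, empty, empty))
  sim <- generate_methylomes(cfg, seed = 5, keep_true_beta = TRUE)
  err <- abs(sim$cohort$beta - sim$truth$true_beta)
  expect_lt(max(err), 0.02)
})

test_that("expression counts carry the planted fold changes", {
  cfg <- tiny_config()
  labels <- rep(1:3, c(5, 4, 3))
  ex <- generate_expression(cfg, labels, seed = 11)
  expect_equal(dim(ex$counts), c(1200L, 12L))
  # near-Poisson limit: per-group means track the configured baseline
  cfg0 <- tiny_config(nb_dispersion = 1e-6)
  ex0 <- generate_expression(cfg0, labels, seed = 11)
  base <- ex0$counts[setdiff(rownames(ex0$counts),
                             ex0$truth_de$gene_id), ]
  grp_means <- sapply(1:3, function(g) mean(base[, labels == g]))
  expect_lt(max(abs(grp_means / mean(grp_means) - 1)), 0.05)
  # planted log2 fold change recovered from group means over planted genes
  up <- ex$truth_de$gene_id[ex$truth_de$group == 1 & ex$truth_de$log2fc > 0]
  m_in <- rowMeans(ex$counts[up, labels == 1, drop = FALSE])
  m_out <- rowMeans(ex$counts[up, labels != 1, drop = FALSE])
  expect_lt(abs(mean(log2(m_in / m_out)) - cfg$de_log2fc), 0.2)
  # determinism
  ex2 <- generate_expression(cfg, labels, seed = 11)
  expect_identical(ex$counts, ex2$counts)
  # too many DE genes is rejected
  expect_error(generate_expression(tiny_config(de_genes_per_group = 500),
                                   labels, seed = 1),
               "exceeds n_genes")
})

test_that("metadata matches the configured group-level distributions", {
  cfg <- synthetic_config(n_samples = 30000,
                          group_proportions = c(1, 1, 1) / 3)
  labels <- rep(1:3, each = 10000)
  md <- generate_metadata(cfg, labels, seed = 13)
  means <- tapply(md$mitotic_index, labels, mean)
  expect_lt(abs(means[[2]] - 6), 0.1)
  expect_lt(abs(means[[1]] - 1), 0.1)
  expect_lt(abs(means[[3]] - 1), 0.1)
  expect_true(all(md$who_grade %in% 1:3))
  high <- tapply(md$who_grade >= 2, labels, mean)
  expect_lt(abs(high[[2]] - 0.8), 0.02)
  expect_lt(abs(high[[1]] - 0.15), 0.02)
  md2 <- generate_metadata(cfg, labels, seed = 13)
  expect_identical(md, md2)
})

test_that("a written cohort reads back identically", {
  sim <- generate_cohort(tiny_config(), seed = 17)
  d <- withr::local_tempdir()
  write_cohort(sim, d)
  back <- read_cohort_dir(d)
  expect_equal(back$cohort$n_meth, sim$cohort$n_meth, ignore_attr = TRUE)
  expect_equal(back$cohort$n_total, sim$cohort$n_total, ignore_attr = TRUE)
  expect_equal(back$cohort$sites$start, sim$cohort$sites$start)
  expect_equal(back$counts, sim$expression$counts)
  expect_equal(unname(back$lengths), unname(sim$expression$lengths))
  expect_equal(back$metadata$who_grade, sim$metadata$who_grade)
  expect_equal(unlist(back$truth$labels), sim$truth$labels,
               ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(group_proportions = c(0.5, 0.4)),
               "sum to 1")
  expect_error(synthetic_config(mitotic_index_means = c(1, 6)),
               "one entry per group")
  expect_error(
    synthetic_config(cnv_segments = list(
      data.frame(chrom = "chr1", start = -5, end = 100, multiplier = 1.5),
      data.frame(chrom = "chr1", start = 0, end = 1, multiplier = 1),
      data.frame(chrom = "chr1", start = 0, end = 1, multiplier = 1))),
    "chromosome bounds")
})
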