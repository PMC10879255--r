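test_that("context track has exact 2 kb shore and shelf flanks", {
  isl <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  tr <- build_context_track(isl, c(chr1 = 1e6))
  width_of <- function(ctx) sum((tr$end - tr$start)[tr$context == ctx])
  expect_equal(width_of("island"), 1000)
  expect_equal(width_of("shore"), 4000)
  expect_equal(width_of("shelf"), 4000)
  expect_equal(width_of("open_sea"), 1e6 - 9000)
  # flank geometry, base by base
  expect_true(any(tr$start == 8000 & tr$end == 10000 &
                    tr$context == "shore"))
  expect_true(any(tr$start == 11000 & tr$end == 13000 &
                    tr$context == "shore"))
  expect_true(any(tr$start == 6000 & tr$end == 8000 &
                    tr$context == "shelf"))
  expect_true(any(tr$start == 13000 & tr$end == 15000 &
                    tr$context == "shelf"))
})

test_that("context precedence and boundary clipping follow the rules", {
  # two islands 1000 bp apart: the gap is entirely shore (beats shelf)
  isl <- data.frame(chrom = "chr1", start = c(10000, 12000),
                    end = c(11000, 13000))
  tr <- build_context_track(isl, c(chr1 = 1e5))
  gap <- tr[tr$start >= 11000 & tr$end <= 12000, ]
  expect_equal(unique(gap$context), "shore")
  expect_equal(sum(gap$end - gap$start), 1000)
  # island at the chromosome start: left flanks clipped away
  tr2 <- build_context_track(data.frame(chrom = "chr1", start = 0,
                                        end = 500), c(chr1 = 1e5))
  expect_equal(tr2$context[1], "island")
  expect_true(any(tr2$start == 500 & tr2$end == 2500 &
                    tr2$context == "shore"))
  expect_error(build_context_track(data.frame(chrom = "chr1", start = 0,
                                              end = 2e5), c(chr1 = 1e5)),
               "bounds")
})

test_that("context track partitions every chromosome (IRanges oracle)", {
  skip_if_not_installed("IRanges")
  set.seed(21)
  starts <- sort(sample(seq(0, 9e4, by = 100), 8))
  isl <- data.frame(chrom = "chr1", start = starts, end = starts + 800)
  lens <- c(chr1 = 1e5, chr2 = 5e4)
  tr <- build_context_track(isl, lens)
  for (ch in names(lens)) {
    sub <- tr[tr$chrom == ch, ]
    expect_equal(sub$start[1], 0)
    expect_equal(sub$end[nrow(sub)], unname(lens[[ch]]))
    expect_true(all(sub$start[-1] == sub$end[-nrow(sub)]))  # no gaps/overlap
  }
  # oracle: reconstruct each class with IRanges set operations
  ir <- function(s, e) IRanges::IRanges(s + 1, e)  # 0-based -> 1-based
  isl_r <- IRanges::reduce(ir(isl$start, isl$end))
  ext2 <- IRanges::restrict(isl_r + 2000, 1, 1e5)
  ext4 <- IRanges::restrict(isl_r + 4000, 1, 1e5)
  shore_r <- IRanges::setdiff(ext2, isl_r)
  shelf_r <- IRanges::setdiff(ext4, ext2)
  got <- tr[tr$chrom == "chr1", ]
  for (cls in list(c("island", "isl_r"), c("shore", "shore_r"),
                   c("shelf", "shelf_r"))) {
    g <- got[got$context == cls[1], ]
    oracle <- get(cls[2])
    expect_equal(g$start, IRanges::start(oracle) - 1)
    expect_equal(g$end, IRanges::end(oracle))
  }
})

test_that("HMR caller merges hypomethylated runs by the stated rules", {
  mk <- function(start, beta, cov = 30) {
    data.frame(chrom = "chr1", start = start, beta = beta, n_total = cov)
  }
  # five consecutive low sites, 100 bp apart -> one HMR
  m <- mk(seq(1000, 1400, by = 100), rep(0.1, 5))
  h <- call_hmrs(m)
  expect_equal(nrow(h), 1)
  expect_equal(h$n_cpgs, 5L)
  expect_equal(h$start, 1000)
  expect_equal(h$end, 1401)
  expect_equal(h$mean_beta, 0.1)
  # 3 low sites, 600 bp gap, 3 low sites: two candidates, both < min_cpgs
  m2 <- mk(c(0, 100, 200, 800, 900, 1000), rep(0.05, 6))
  expect_equal(nrow(call_hmrs(m2, max_gap = 500, min_cpgs = 4)), 0)
  expect_equal(nrow(call_hmrs(m2, max_gap = 500, min_cpgs = 3)), 2)
  # fully methylated -> nothing
  expect_equal(nrow(call_hmrs(mk(1:10 * 100, rep(0.9, 10)))), 0)
  # low-coverage sites are not hypo-eligible: skipped, not counted
  m3 <- mk(seq(0, 400, by = 100), rep(0.1, 5),
           cov = c(30, 30, 2, 30, 30))
  h3 <- call_hmrs(m3, min_cpgs = 4)
  expect_equal(h3$n_cpgs, 4L)
  # but they do break a run when the remaining hypo gap exceeds max_gap
  m4 <- mk(c(0, 100, 200, 760, 860, 960), rep(0.1, 6),
           cov = c(30, 30, 30, 2, 30, 30))
  expect_equal(nrow(call_hmrs(m4, min_cpgs = 3)), 1)
  expect_equal(call_hmrs(m4, min_cpgs = 3)$n_cpgs, 3L)
  expect_error(call_hmrs(m2[c(2, 1, 3:6), ]), "sorted")
})

test_that("HMR annotation assigns context by maximal overlap and element by precedence", {
  isl <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  tr <- build_context_track(isl, c(chr1 = 1e5))
  genes <- data.frame(chrom = "chr1", start = 30000, end = 40000,
                      name = "gA", score = 0, strand = "+")
  exons <- data.frame(chrom = "chr1", start = c(30000, 36000),
                      end = c(31000, 37000), name = c("e1", "e2"))
  hmrs <- data.frame(
    chrom = "chr1",
    start = c(10000, 11500, 50000, 28500, 33000, 36500),
    end = c(11000, 14500, 50500, 29500, 34000, 37500),
    n_cpgs = 5L, mean_beta = 0.1,
    sample_id = "S01", stringsAsFactors = FALSE)
  ann <- annotate_hmrs(hmrs, tr, genes, exons)
  expect_equal(ann$hmrs$context,
               c("island",   # exact island
                 "shore",    # 1500 bp shore vs 1500 bp shelf: tie -> shore
                 "open_sea", "open_sea", "open_sea", "open_sea"))
  # promoter beats gene body; exon beats intron; intron inside gene
  expect_equal(ann$hmrs$element,
               c("intergenic", "intergenic", "intergenic",
                 "promoter",   # overlaps [28000, 30500)
                 "intron",     # gene body, no exon overlap
                 "exon"))      # overlaps exon 2
  expect_true(ann$hmrs$island_or_shore_any[1])
  s <- ann$summary
  expect_equal(s$n_hmrs, 6L)
  expect_equal(s$frac_island_or_shore, 2 / 6)
  expect_equal(s$n_promoter, 1L)
  expect_equal(s$n_exon, 1L)
  expect_equal(s$n_intron, 1L)
  # empty input -> empty summary, not an error
  empty <- annotate_hmrs(hmrs[0, ], tr, genes, exons)
  expect_equal(nrow(empty$summary), 0)
})

test_that("HMR half in shore, half in open sea is assigned shore", {
  isl <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  tr <- build_context_track(isl, c(chr1 = 1e5))
  # [12000, 14000): 1000 bp shore + 1000 bp shelf -> tie -> shore precedence
  hm <- data.frame(chrom = "chr1", start = 12000, end = 14000,
                   n_cpgs = 4L, mean_beta = 0.2, sample_id = "S01")
  expect_equal(annotate_hmrs(hm, tr)$hmrs$context, "shore")
  # [11000, 15000): 2000 shore + 2000 shelf -> tie resolved to shore
  hm2 <- data.frame(chrom = "chr1", start = 11000, end = 15000,
                    n_cpgs = 4L, mean_beta = 0.2, sample_id = "S01")
  expect_equal(annotate_hmrs(hm2, tr)$hmrs$context, "shore")
})

test_that("CNV segmentation returns flat neutral profiles for identical coverage", {
  ns <- 80
  n_total <- matrix(30L, ns, 4)
  co <- manual_cohort(rep(c("chr1", "chr2"), each = ns / 2),
                      rep(seq(0, 39) * 25000, 2),
                      matrix(15L, ns, 4), n_total,
                      c(chr1 = 1e6, chr2 = 1e6))
  segs <- call_cnvs(co, bin_size = 1e5, min_bins = 2)
  expect_equal(nrow(segs), 4 * 2)  # one segment per chromosome per sample
  expect_true(all(segs$call == "neutral"))
  expect_equal(max(abs(segs$mean_log2_ratio)), 0)
  # segments tile each chromosome
  expect_true(all(segs$start == 0 & segs$end == 1e6))
  expect_equal(unname(genome_fraction_cnv(segs, co$chrom_lengths)),
               rep(0, 4))
})

test_that("an infinite split threshold yields whole-chromosome segments", {
  sim <- generate_methylomes(tiny_config(), seed = 23)
  segs <- call_cnvs(sim$cohort, bin_size = 1e5, t_threshold = Inf,
                    min_bins = 2)
  per <- table(segs$sample_id, segs$chrom)
  expect_true(all(per == 1))
  # lowering the call cutoff never decreases the affected genome fraction
  segs2 <- call_cnvs(sim$cohort, bin_size = 1e5, min_bins = 2)
  f_strict <- genome_fraction_cnv(segs2, sim$cohort$chrom_lengths)
  segs3 <- call_cnvs(sim$cohort, bin_size = 1e5, min_bins = 2,
                     call_cutoff = 0.1)
  f_loose <- genome_fraction_cnv(segs3, sim$cohort$chrom_lengths)
  expect_true(all(f_loose >= f_strict - 1e-12))
})

test_that("genome fraction arithmetic and overlap detection work", {
  segs <- data.frame(sample_id = "S01", chrom = c("chrA", "chrB"),
                     start = c(0, 0), end = c(2e6, 18e6),
                     n_bins = 4L, mean_log2_ratio = c(0.6, 0),
                     call = c("gain", "neutral"))
  expect_equal(unname(genome_fraction_cnv(segs, c(chrA = 2e6, chrB = 18e6))),
               0.1)
  # invariant to chromosome ordering
  expect_equal(unname(genome_fraction_cnv(segs[2:1, ],
                                          c(chrB = 18e6, chrA = 2e6))),
               0.1)
  bad <- rbind(segs, data.frame(sample_id = "S01", chrom = "chrA",
                                start = 1e6, end = 3e6, n_bins = 2L,
                                mean_log2_ratio = 0, call = "neutral"))
  expect_error(genome_fraction_cnv(bad, c(chrA = 3e6, chrB = 18e6)),
               "overlapping")
})

test_that("the HMR-enriched group carries more HMRs (generator property)", {
  sim <- generate_methylomes(tiny_config(), seed = 29)
  hmrs <- call_hmrs_cohort(sim$cohort)
  counts <- table(factor(hmrs$sample_id, levels = sim$cohort$sample_ids))
  by_group <- tapply(as.integer(counts), sim$truth$labels, mean)
  expect_gt(by_group[["2"]], by_group[["1"]])
  expect_gt(by_group[["2"]], by_group[["3"]])
})
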