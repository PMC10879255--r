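test_that("feature selection ranks sites by across-sample variance", {
  n_meth <- cbind(c(0L, 5L, 2L), c(10L, 5L, 4L), c(0L, 5L, 6L),
                  c(10L, 5L, 8L))
  n_total <- matrix(10L, 3, 4)
  co <- manual_cohort(rep("chr1", 3), c(100, 200, 300),
                      n_meth, n_total, c(chr1 = 1000), min_coverage = 5)
  # variances: site1 bimodal (high), site2 zero, site3 intermediate
  # too few usable sites overall -> error
  expect_error(select_features(co, 2), "fewer than 10 usable")
  co10 <- manual_cohort(rep("chr1", 12), seq(100, 1200, by = 100),
                        rbind(n_meth, n_meth, n_meth, n_meth),
                        matrix(10L, 12, 4), c(chr1 = 2000))
  X <- select_features(co10, 4)
  expect_equal(ncol(X), 4)
  # the four bimodal sites (variance 1/3) are selected, in genomic order
  expect_equal(colnames(X), paste0("chr1:", c(100, 400, 700, 1000)))
  expect_warning(select_features(co10, 50), "using all")
  co0 <- manual_cohort(rep("chr1", 12), seq(100, 1200, by = 100),
                       matrix(5L, 12, 4), matrix(10L, 12, 4),
                       c(chr1 = 2000))
  expect_error(select_features(co0, 4), "degenerate")
})

test_that("k-means recovers two point clouds with the hand-computed objective", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0),
             c(10, 10), c(10, 11), c(11, 10))
  fit <- kmeans_lloyd(X, 2, n_restarts = 10, seed = 1)
  expect_equal(fit$labels[1:3], rep(fit$labels[1], 3))
  expect_equal(fit$labels[4:6], rep(fit$labels[4], 3))
  expect_false(fit$labels[1] == fit$labels[4])
  # oracle: sum of squared deviations from the known cluster means
  ss_oracle <- sum(scale(X[1:3, ], scale = FALSE)^2) +
    sum(scale(X[4:6, ], scale = FALSE)^2)
  expect_equal(fit$within_ss, ss_oracle, tolerance = 1e-9)
  # independent cross-check: stats::kmeans reaches the same optimum
  ref <- stats::kmeans(X, 2, nstart = 10)
  expect_equal(fit$within_ss, ref$tot.withinss, tolerance = 1e-9)
})

test_that("k-means edge cases behave as contracted", {
  set.seed(42)
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(kmeans_lloyd(X, 5, seed = 1)$within_ss, 0, tolerance = 1e-9)
  expect_error(kmeans_lloyd(X, 0), "k must be")
  expect_error(kmeans_lloyd(X, 6, seed = 1), "exceed")
  f1 <- kmeans_lloyd(X, 2, seed = 7)
  f2 <- kmeans_lloyd(X, 2, seed = 7)
  expect_identical(f1$labels, f2$labels)
})

test_that("the two dispersion forms satisfy the algebraic identity", {
  set.seed(11)
  X <- matrix(rnorm(40), 10, 4)
  for (k in 1:3) {
    lab <- kmeans_lloyd(X, k, seed = k)$labels
    expect_equal(within_dispersion(X, lab, "ss"),
                 within_dispersion(X, lab, "pairwise"), tolerance = 1e-9)
  }
})

test_that("consensus matrices are valid and sharp on separated clouds", {
  cl <- make_clouds(rbind(c(0, 0, 0), c(20, 20, 20)), n_per = 6, seed = 2)
  cr <- consensus_cluster(cl$X, k_range = 2:3, H = 30, seed = 3)
  C2 <- cr$consensus[[1]]
  expect_true(all(C2 >= 0 & C2 <= 1))
  expect_equal(C2, t(C2))
  expect_equal(unname(diag(C2)), rep(1, 12))
  within <- C2[cl$labels == 1, cl$labels == 1]
  across <- C2[cl$labels == 1, cl$labels == 2]
  expect_true(all(within == 1))
  expect_true(all(across == 0))
  expect_error(consensus_cluster(cl$X, H = 1), "H must be")
  expect_error(consensus_cluster(cl$X[1:3, ], k_range = 2:6), "samples")
})

test_that("CDF area matches the two-point closed form and delta definitions", {
  fake <- function(q, n = 10) {
    # consensus with fraction q of upper-triangle entries at 0, rest at 1
    m <- n * (n - 1) / 2
    v <- c(rep(0, round(q * m)), rep(1, m - round(q * m)))
    C <- matrix(0, n, n)
    C[upper.tri(C)] <- v
    C <- C + t(C); diag(C) <- 1
    C
  }
  cr <- structure(list(consensus = list(fake(0.4), fake(0.6), fake(0.6)),
                       k_range = 2:4, H = 10, p = 0.8),
                  class = "ConsensusResult")
  tab <- cdf_area(cr)
  expect_equal(tab$area, c(0.4, 0.6, 0.6), tolerance = 1e-12)
  expect_equal(tab$delta[1], tab$area[1])      # delta(2) = A(2)
  expect_equal(tab$delta[2], 0.2 / 0.4, tolerance = 1e-12)
  expect_equal(tab$delta[3], 0)
  const <- structure(list(consensus = list(fake(0)), k_range = 2,
                          H = 10, p = 0.8), class = "ConsensusResult")
  expect_equal(cdf_area(const)$area, 0)  # all entries identical
  gappy <- structure(list(consensus = list(fake(0.4), fake(0.6)),
                          k_range = c(2, 4), H = 10, p = 0.8),
                     class = "ConsensusResult")
  expect_error(cdf_area(gappy), "missing k")
})

test_that("gap statistic selects k on low-dimensional Monte-Carlo cases", {
  # single spherical cloud: k_hat = 1 in >= 8/10 seeds
  hits1 <- 0
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(250), 50, 5)
    g <- gap_statistic(X, k_range = 1:5, B = 50, seed = 100 + s)
    hits1 <- hits1 + (g$k_hat == 1)
  }
  expect_gte(hits1, 8)
  # three well-separated clouds: k_hat = 3 in >= 9/10 seeds
  hits3 <- 0
  for (s in 1:10) {
    cl <- make_clouds(rbind(c(0, 0, 0, 0, 0), c(15, 0, 0, 0, 0),
                            c(0, 15, 0, 0, 0)), n_per = 15, seed = s)
    g <- gap_statistic(cl$X, k_range = 1:5, B = 50, seed = 200 + s)
    hits3 <- hits3 + (g$k_hat == 3)
  }
  expect_gte(hits3, 9)
  expect_error(gap_statistic(matrix(rnorm(20), 5, 4), B = 1), "B must be")
})

test_that("the robust jump rule reads flat, creeping and jumped gap curves", {
  mk_gap <- function(gap, s = rep(0.003, length(gap))) {
    structure(list(k_range = seq_along(gap), W = exp(-gap), logW = -gap,
                   ElogWstar = rep(0, length(gap)), gap = gap, s = s,
                   k_hat = NA, B = 50), class = "GapResult")
  }
  # monotone creep (structureless high-dimensional case) -> k_min
  expect_equal(gap_k_robust(mk_gap(c(0.40, 0.41, 0.42, 0.43, 0.44))), 1)
  # two real jumps then creep -> true k = 3
  expect_equal(gap_k_robust(mk_gap(c(-0.7, 0.25, 3.07, 3.073, 3.074))), 3)
  expect_equal(gap_k_robust(mk_gap(c(-0.7, 0.25, 3.07, 3.073, 3.074)),
                            k_min = 2), 3)
  # flat noise -> no evidence for structure
  expect_equal(gap_k_robust(mk_gap(c(0.1, 0.101, 0.099, 0.1, 0.102))), 1)
})

test_that("hierarchical clustering agrees with k-means on separated clouds", {
  X <- rbind(c(0, 0), c(0.2, 0), c(10, 10), c(10.2, 10))
  hc <- hierarchical_cluster(X, 2)
  expect_equal(hc$labels[1], hc$labels[2])
  expect_equal(hc$labels[3], hc$labels[4])
  expect_false(hc$labels[1] == hc$labels[3])
  expect_equal(sort(hc$order), 1:4)
  expect_equal(length(unique(hierarchical_cluster(X, 4)$labels)), 4)
  expect_error(hierarchical_cluster(rbind(c(NA, 1), c(0, 1)), 1), "finite")
  cl <- make_clouds(rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0)),
                    n_per = 8, seed = 4)
  km <- kmeans_lloyd(cl$X, 3, seed = 5)$labels
  hl <- hierarchical_cluster(cl$X, 3)$labels
  expect_equal(adjusted_rand_index(km, hl), 1)
})

test_that("PCA embedding is exact on rank-2 data and centered", {
  set.seed(6)
  basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  scores <- cbind(rnorm(20, sd = 4), rnorm(20, sd = 1))
  X <- scores %*% t(basis)  # data lies exactly in a 2-D plane
  emb <- embed_samples(X, "pca")
  expect_equal(colMeans(emb), c(dim1 = 0, dim2 = 0), tolerance = 1e-8)
  # pairwise distances are preserved exactly for rank-2 data
  expect_equal(as.matrix(dist(emb)), as.matrix(dist(scale(X, scale = FALSE))),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(embed_samples(X, "pcoa"), "arg")
  expect_error(embed_samples(X[1:2, ], "pca"), "at least 3")
})

test_that("embeddings separate planted clouds (silhouette)", {
  skip_if_not_installed("cluster")
  cl <- make_clouds(rbind(c(0, 0, 0, 0), c(12, 0, 0, 0), c(0, 12, 0, 0)),
                    n_per = 10, seed = 8)
  for (method in c("pca", "umap")) {
    if (method == "umap") skip_if_not_installed("uwot")
    emb <- embed_samples(cl$X, method, seed = 9)
    expect_equal(dim(emb), c(30L, 2L))
    sil <- cluster::silhouette(cl$labels, dist(emb))
    expect_gt(mean(sil[, "sil_width"]), 0.5)
  }
})

test_that("select_k combines the two criteria deterministically", {
  cl <- make_clouds(rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0)),
                    n_per = 8, seed = 10)
  cons <- consensus_cluster(cl$X, k_range = 2:4, H = 30, seed = 11)
  gap <- gap_statistic(cl$X, k_range = 1:4, B = 30, seed = 12)
  s1 <- select_k(cons, gap)
  s2 <- select_k(cons, gap)
  expect_identical(unclass(s1), unclass(s2))
  expect_equal(s1$k, 3)
  expect_true(s1$concordant)
  far <- data.frame(k = 8:9, area = c(0.5, 0.6), delta = c(0.5, 0.2))
  expect_error(select_k(far, gap), "disjoint")
})

test_that("group assignment renumbers by size and ignores row order", {
  set.seed(13)
  # clouds of unequal sizes 6 / 4 / 2
  X <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
             matrix(rnorm(8, 10, 0.1), 4, 2),
             cbind(rnorm(2, 0, 0.1), rnorm(2, 10, 0.1)))
  lab <- assign_groups(X, 3, seed = 14)
  expect_equal(unname(lab), rep(c(1L, 2L, 3L), c(6, 4, 2)))
  # permutation invariance of the partition
  perm <- sample(nrow(X))
  lab_p <- assign_groups(X[perm, ], 3, seed = 14)
  expect_equal(adjusted_rand_index(lab_p, lab[perm]), 1)
  expect_equal(unname(assign_groups(X, 1)), rep(1L, nrow(X)))
  expect_error(assign_groups(X[1:2, ], 3), "exceed")
})

test_that("adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(15)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2L, 3L, 4L, 5L, 1L)), 1)
})
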