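#' Select high-variance CpG features for clustering
#'
#' Builds the samples x features beta matrix from the CpG sites with the
#' highest across-sample variance. Sites that are masked (below the
#' cohort's minimum coverage) or missing in any sample are excluded before
#' ranking; ties in variance are broken by genomic order.
#'
#' @param cohort a \code{MethylationCohort}.
#' @param n_top number of top-variance sites to keep (default 5000); if more
#'   than the number of usable sites, all are kept with a warning.
#' @return numeric matrix (samples x features), rownames = sample ids,
#'   colnames = \code{chrom:start} site ids.
#' @export
select_features <- function(cohort, n_top = 5000) {
  if (length(cohort$sample_ids) < 2) stop("need at least 2 samples")
  usable <- rowSums(cohort$n_total < cohort$min_coverage) == 0 &
    rowSums(!is.finite(cohort$beta)) == 0
  if (sum(usable) < 10) stop("fewer than 10 usable CpG sites")
  b <- cohort$beta[usable, , drop = FALSE]
  mu <- rowMeans(b)
  v <- rowSums((b - mu)^2) / (ncol(b) - 1)
  if (all(v == 0)) stop("degenerate feature matrix: all site variances are zero")
  if (n_top > length(v)) {
    warning("n_top exceeds available sites; using all ", length(v), " sites")
    n_top <- length(v)
  }
  keep <- order(-v, seq_along(v))[seq_len(n_top)]
  keep <- sort(keep)  # features in genomic order
  X <- t(b[keep, , drop = FALSE])
  rownames(X) <- cohort$sample_ids
  colnames(X) <- paste0(cohort$sites$chrom[usable][keep], ":",
                        cohort$sites$start[usable][keep])
  X
}

# Lloyd's k-means expressed on the Gram matrix G = X X'. Squared distance
# from point i to the centroid of cluster c is
#   G_ii - 2 mean_{j in c} G_ij + mean_{j,l in c} G_jl,
# so subsampled consensus runs only ever index into one precomputed G.
.gram_kmeans <- function(G, k, n_restarts = 20, max_iter = 100) {
  n <- nrow(G)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k cannot exceed the number of samples")
  dG <- diag(G)
  assign_step <- function(z) {
    sizes <- tabulate(z, k)
    Msum <- rowsum(G, z)                      # k x n
    m <- Msum / sizes
    S <- rowsum(t(Msum), z)                   # k x k
    q <- diag(S) / sizes^2
    D <- matrix(dG, n, k) - 2 * t(m) + matrix(q, n, k, byrow = TRUE)
    list(D = D, q = q)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- sample.int(n, k)
    D <- matrix(dG, n, k) - 2 * G[, init, drop = FALSE] +
      matrix(dG[init], n, k, byrow = TRUE)
    z <- max.col(-D, ties.method = "first")
    z <- .repair_empty(z, D, k)
    for (it in seq_len(max_iter)) {
      st <- assign_step(z)
      znew <- max.col(-st$D, ties.method = "first")
      znew <- .repair_empty(znew, st$D, k)
      if (identical(znew, z)) break
      z <- znew
    }
    st <- assign_step(z)
    ss <- sum(pmax(st$D[cbind(seq_len(n), z)], 0))
    if (is.null(best) || ss < best$within_ss - 1e-12)
      best <- list(labels = z, within_ss = ss)
  }
  if (any(tabulate(best$labels, k) == 0))
    stop("empty cluster after repair")
  best
}

# Empty-cluster repair: the point farthest from its assigned centroid
# becomes the empty cluster (never stealing from a singleton).
.repair_empty <- function(z, D, k) {
  sizes <- tabulate(z, k)
  while (any(sizes == 0)) {
    empty <- which(sizes == 0)[1]
    d_assigned <- D[cbind(seq_along(z), z)]
    d_assigned[sizes[z] <= 1] <- -Inf
    far <- which.max(d_assigned)
    z[far] <- empty
    sizes <- tabulate(z, k)
  }
  z
}

#' K-means clustering (Lloyd's algorithm, best of random restarts)
#'
#' Squared-Euclidean objective; initialization by k distinct data rows;
#' empty clusters repaired by reassigning the farthest point. The best of
#' \code{n_restarts} runs (lowest within-cluster sum of squares) is kept.
#'
#' @param X numeric matrix (samples x features), all finite.
#' @param k number of clusters, \code{1 <= k <= nrow(X)}.
#' @param n_restarts random restarts (default 20).
#' @param seed optional seed for reproducibility.
#' @param max_iter iteration cap per restart.
#' @return list with \code{labels} (1..k), \code{centers} (k x features) and
#'   \code{within_ss}.
#' @export
kmeans_lloyd <- function(X, k, n_restarts = 20, seed = NULL,
                         max_iter = 100) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (!is.null(seed)) set.seed(seed)
  fit <- .gram_kmeans(tcrossprod(X), k, n_restarts, max_iter)
  centers <- rowsum(X, fit$labels) / tabulate(fit$labels, k)
  list(labels = fit$labels, centers = centers, within_ss = fit$within_ss)
}

#' Within-cluster dispersion of a partition
#'
#' Two algebraically identical forms of W: \code{"ss"} sums squared
#' deviations from cluster centroids; \code{"pairwise"} computes
#' \code{sum_r (1/(2 n_r)) sum_{i,j in C_r} d2(i,j)} with squared Euclidean
#' distances. Their equality is the standard dispersion identity.
#'
#' @param X samples x features matrix.
#' @param labels integer cluster labels.
#' @param method which form to evaluate.
#' @return scalar dispersion W.
#' @export
within_dispersion <- function(X, labels, method = c("ss", "pairwise")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "ss") {
    sizes <- tabulate(labels, max(labels))
    centers <- rowsum(X, labels) / sizes[sizes > 0]
    sum((X - centers[match(labels, sort(unique(labels))), , drop = FALSE])^2)
  } else {
    d2 <- as.matrix(stats::dist(X))^2
    w <- 0
    for (c in unique(labels)) {
      idx <- which(labels == c)
      w <- w + sum(d2[idx, idx]) / (2 * length(idx))
    }
    w
  }
}

#' Consensus k-means clustering over subsampling resamples
#'
#' For each k, repeatedly subsamples a fraction \code{p} of samples without
#' replacement, clusters the subsample with [kmeans_lloyd()], and records
#' co-clustering. The consensus matrix entry \code{C_k(i,j)} is the number
#' of times i and j were clustered together divided by the number of times
#' both were sampled; its diagonal is 1. Pairs never co-sampled (vanishing
#' probability at the defaults) are set to the neutral value 0.5 with a
#' warning.
#'
#' @param X samples x features matrix.
#' @param k_range candidate cluster numbers (default 2:6).
#' @param H number of resamples (default 100).
#' @param p subsample fraction (default 0.8).
#' @param seed optional seed.
#' @param n_restarts k-means restarts per resample.
#' @return object of class \code{ConsensusResult}: list with
#'   \code{consensus} (one matrix per k), \code{k_range}, \code{H}, \code{p}.
#' @export
consensus_cluster <- function(X, k_range = 2:6, H = 100, p = 0.8,
                              seed = NULL, n_restarts = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (H < 2) stop("H must be >= 2")
  if (n < max(k_range) + 1)
    stop("need at least max(k_range) + 1 samples")
  if (!is.null(seed)) set.seed(seed)
  G <- tcrossprod(X)
  m_sub <- ceiling(p * n)
  out <- vector("list", length(k_range))
  names(out) <- paste0("k", k_range)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    M <- matrix(0, n, n)
    Icnt <- matrix(0, n, n)
    for (h in seq_len(H)) {
      sub <- sort(sample.int(n, m_sub))
      z <- .gram_kmeans(G[sub, sub, drop = FALSE], k, n_restarts)$labels
      Icnt[sub, sub] <- Icnt[sub, sub] + 1
      for (c in seq_len(k)) {
        idx <- sub[z == c]
        M[idx, idx] <- M[idx, idx] + 1
      }
    }
    C <- M / Icnt
    never <- !is.finite(C)
    diag(never) <- FALSE
    if (any(never)) {
      warning(sum(never) / 2, " sample pair(s) never co-sampled; ",
              "consensus set to 0.5")
      C[never] <- 0.5
    }
    diag(C) <- 1
    dimnames(C) <- list(rownames(X), rownames(X))
    out[[ki]] <- C
  }
  structure(list(consensus = out, k_range = k_range, H = H, p = p),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: k in {%s}, H = %d resamples, p = %.2f\n",
              paste(x$k_range, collapse = ", "), x$H, x$p))
  invisible(x)
}

#' Area under the consensus CDF and its relative change
#'
#' For each k, the empirical CDF over the \code{n(n-1)/2} upper-triangle
#' consensus entries is integrated:
#' \code{A(k) = sum_i (x_i - x_{i-1}) CDF(x_{i-1})} over the sorted distinct
#' entry values. The relative delta-area is \code{delta(k_min) = A(k_min)}
#' and \code{delta(k) = (A(k) - A(k-1)) / A(k-1)} for larger k; an elbow in
#' delta marks the k beyond which added clusters no longer improve
#' stability.
#'
#' @param cr a \code{ConsensusResult}.
#' @return data.frame with columns \code{k}, \code{area}, \code{delta}.
#' @export
cdf_area <- function(cr) {
  stopifnot(inherits(cr, "ConsensusResult"))
  ks <- cr$k_range
  if (length(ks) > 1 && any(diff(ks) != 1))
    stop("k_range must be contiguous to compute delta(k): missing k - 1")
  area <- vapply(seq_along(ks), function(i) {
    v <- cr$consensus[[i]][upper.tri(cr$consensus[[i]])]
    x <- sort(unique(v))
    if (length(x) < 2) return(0)
    cdf <- stats::ecdf(v)
    sum(diff(x) * cdf(x[-length(x)]))
  }, numeric(1))
  delta <- c(area[1], if (length(ks) > 1) diff(area) / area[-length(area)])
  data.frame(k = ks, area = area, delta = delta)
}

#' Gap statistic for the number of clusters
#'
#' Computes the within-cluster dispersion \code{W_k} for each k on the data
#' and on \code{B} Monte-Carlo reference datasets with each feature drawn
#' uniformly over its observed range, then
#' \code{Gap(k) = mean_b log W*_kb - log W_k} and
#' \code{s_k = sd_b(log W*_kb) sqrt(1 + 1/B)}. The selected \code{k_hat} is
#' the smallest k with \code{Gap(k) >= Gap(k+1) - s_{k+1}} (one standard
#' error rule), falling back to \code{argmax Gap}.
#'
#' @param X samples x features matrix.
#' @param k_range candidate k (default 1:6).
#' @param B number of reference datasets (default 50).
#' @param seed optional seed.
#' @param n_restarts k-means restarts.
#' @return object of class \code{GapResult}: list with \code{k_range},
#'   \code{W}, \code{logW}, \code{ElogWstar}, \code{gap}, \code{s},
#'   \code{k_hat}, \code{B}.
#' @export
gap_statistic <- function(X, k_range = 1:6, B = 50, seed = NULL,
                          n_restarts = 20) {
  X <- as.matrix(X)
  if (B < 2) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  fit_ws <- function(M) {
    G <- tcrossprod(M)
    vapply(k_range, function(k) .gram_kmeans(G, k, n_restarts)$within_ss,
           numeric(1))
  }
  W <- fit_ws(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  n <- nrow(X); pdim <- ncol(X)
  logWstar <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    Xb <- matrix(stats::runif(n * pdim, rep(lo, each = n),
                              rep(hi, each = n)), n, pdim)
    logWstar[b, ] <- log(fit_ws(Xb))
  }
  logW <- log(W)
  Elog <- colMeans(logWstar)
  gap <- Elog - logW
  s <- apply(logWstar, 2, stats::sd) * sqrt(1 + 1 / B)
  k_hat <- .gap_rule(k_range, gap, s)
  structure(list(k_range = k_range, W = W, logW = logW, ElogWstar = Elog,
                 gap = gap, s = s, k_hat = k_hat, B = B),
            class = "GapResult")
}

.gap_rule <- function(ks, gap, s) {
  if (length(ks) == 1) return(ks)
  for (i in seq_len(length(ks) - 1)) {
    if (gap[i] >= gap[i + 1] - s[i + 1]) return(ks[i])
  }
  ks[which.max(gap)]
}

#' @export
print.GapResult <- function(x, ...) {
  cat(sprintf("GapResult: k_hat = %d (B = %d references)\n", x$k_hat, x$B))
  print(data.frame(k = x$k_range, logW = round(x$logW, 4),
                   gap = round(x$gap, 4), s = round(x$s, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Agglomerative hierarchical clustering (Euclidean, Ward linkage)
#'
#' Ward's method on Euclidean distances matches the k-means variance
#' objective; the leaf order is returned for heatmap rendering.
#'
#' @param X samples x features matrix.
#' @param k number of clusters to cut to.
#' @return list with \code{labels}, \code{order} (dendrogram leaf order) and
#'   the \code{hclust} object.
#' @export
hierarchical_cluster <- function(X, k) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (nrow(X) < k) stop("need at least k samples")
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(labels = unname(labels), order = hc$order, hclust = hc)
}

#' Two-dimensional embedding of the sample feature matrix
#'
#' \code{"pca"} computes the first two principal axes by singular value
#' decomposition of the column-centered matrix (implemented here);
#' \code{"umap"} and \code{"tsne"} delegate to the uwot and Rtsne packages
#' behind the same contract. Deterministic for a fixed seed.
#'
#' @param X samples x features matrix, \code{nrow(X) >= 3}.
#' @param method one of \code{"pca"}, \code{"umap"}, \code{"tsne"}.
#' @param n_neighbors UMAP neighborhood size (default 15, capped at n - 1).
#' @param seed optional seed.
#' @return n x 2 coordinate matrix, rownames preserved.
#' @export
embed_samples <- function(X, method = c("pca", "umap", "tsne"),
                          n_neighbors = 15, seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (!is.null(seed)) set.seed(seed)
  coords <- switch(method,
    pca = {
      Xc <- sweep(X, 2, colMeans(X))
      sv <- svd(Xc, nu = 2, nv = 2)
      sc <- sv$u %*% diag(sv$d[1:2], 2)
      # deterministic sign: largest-magnitude loading positive per axis
      for (j in 1:2) {
        v <- sv$v[, j]
        if (v[which.max(abs(v))] < 0) sc[, j] <- -sc[, j]
      }
      sc
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("method 'umap' requires the uwot package")
      uwot::umap(X, n_neighbors = min(n_neighbors, nrow(X) - 1),
                 n_components = 2, n_threads = 1, n_sgd_threads = 1)
    },
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("method 'tsne' requires the Rtsne package")
      perp <- max(1, min(30, floor((nrow(X) - 1) / 3)))
      Rtsne::Rtsne(X, dims = 2, perplexity = perp,
                   check_duplicates = FALSE)$Y
    })
  coords <- as.matrix(coords)
  rownames(coords) <- rownames(X)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Robust choice of k from a gap curve (jump rule)
#'
#' The classical one-standard-error rule compares successive gap values
#' against \code{s_k}, the Monte-Carlo standard error of the reference
#' ensemble. With many near-independent features that error becomes
#' vanishingly small (order \code{1/sqrt(n p)}), while the gap increments
#' beyond the true k retain a small systematic positive bias from the
#' cluster optimizer, so the classical rule chases sub-percent gap gains
#' into ever larger k. This rule is self-calibrating instead: it estimates
#' the curve's intrinsic creep as the median gap increment and accepts a k
#' only when the increment into it stands out from that baseline by more
#' than \code{jump_factor} reference standard errors. The selected k is the
#' largest accepted jump; when no increment stands out, the smallest k in
#' range is returned (no evidence for added structure).
#'
#' @param gap a \code{GapResult}.
#' @param k_min smallest k considered (default 1).
#' @param jump_factor multiple of \code{s} an increment must exceed the
#'   baseline creep by (default 2).
#' @return the selected k.
#' @export
gap_k_robust <- function(gap, k_min = 1, jump_factor = 2) {
  stopifnot(inherits(gap, "GapResult"))
  sel <- gap$k_range >= k_min
  ks <- gap$k_range[sel]
  g <- gap$gap[sel]
  s <- gap$s[sel]
  if (length(ks) < 2) return(ks[1])
  inc <- diff(g)
  base <- stats::median(inc)
  qual <- which(inc > base + jump_factor * s[-1])
  if (!length(qual)) return(ks[1])
  ks[max(qual) + 1]
}

#' Combine gap statistic and consensus delta-area into one choice of k
#'
#' The primary decision comes from the gap curve restricted to
#' \code{k >= 2}, using the robust jump rule of [gap_k_robust()] (the
#' classical one-standard-error selection is reported alongside as
#' \code{k_gap_se}; see the methods vignette for why the classical rule
#' drifts on high-dimensional feature matrices). The consensus CDF
#' delta-area corroborates the decision with an elbow rule: the largest
#' \code{k >= 3} whose relative area gain exceeds \code{delta_threshold},
#' else 2. Both are reported together with a concordance flag; discordance
#' is informational, never fatal.
#'
#' @param consensus a \code{ConsensusResult} or the [cdf_area()] table.
#' @param gap a \code{GapResult}.
#' @param delta_threshold relative delta-area threshold (default 0.1).
#' @param jump_factor passed to [gap_k_robust()].
#' @return object of class \code{k_selection}: list with \code{k}
#'   (selected), \code{k_gap} (= \code{k}), \code{k_gap_se} (classical
#'   one-SE rule restricted to k >= 2), \code{k_gap_unrestricted}
#'   (classical rule over the full gap range), \code{k_delta},
#'   \code{concordant}, and the diagnostics table.
#' @export
select_k <- function(consensus, gap, delta_threshold = 0.1,
                     jump_factor = 2) {
  stopifnot(inherits(gap, "GapResult"))
  cdf <- if (inherits(consensus, "ConsensusResult")) cdf_area(consensus)
         else consensus
  if (!length(intersect(cdf$k, gap$k_range)))
    stop("consensus and gap results cover disjoint k ranges")
  sel <- gap$k_range >= 2
  if (!any(sel)) stop("gap result contains no k >= 2")
  k_gap <- gap_k_robust(gap, k_min = 2, jump_factor = jump_factor)
  k_gap_se <- .gap_rule(gap$k_range[sel], gap$gap[sel], gap$s[sel])
  cand <- cdf$k[cdf$k >= 3 & cdf$delta >= delta_threshold]
  k_delta <- if (length(cand)) max(cand) else min(cdf$k)
  diagnostics <- merge(cdf,
                       data.frame(k = gap$k_range, W = gap$W, gap = gap$gap,
                                  s = gap$s),
                       by = "k", all = TRUE)
  structure(list(k = k_gap, k_gap = k_gap, k_gap_se = k_gap_se,
                 k_gap_unrestricted = gap$k_hat, k_delta = k_delta,
                 concordant = identical(as.integer(k_gap),
                                        as.integer(k_delta)),
                 delta_threshold = delta_threshold,
                 diagnostics = diagnostics),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("selected k = %d (gap statistic; delta-area corroboration k = %d, %s)\n",
              x$k, x$k_delta,
              if (x$concordant) "concordant" else "discordant"))
  invisible(x)
}

#' Final group assignment at the selected k
#'
#' K-means on the full feature matrix, best of \code{n_restarts} restarts;
#' group ids are renumbered by descending group size (ties broken by the
#' smallest member sample index), so group 1 is always the largest.
#'
#' @param X samples x features matrix.
#' @param k number of groups.
#' @param seed optional seed.
#' @param n_restarts restarts (default 50).
#' @return integer labels in 1..k, named by rownames of \code{X}.
#' @export
assign_groups <- function(X, k, seed = NULL, n_restarts = 50) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k cannot exceed the number of samples")
  if (k == 1) return(stats::setNames(rep(1L, nrow(X)), rownames(X)))
  fit <- kmeans_lloyd(X, k, n_restarts = n_restarts, seed = seed)
  z <- fit$labels
  sizes <- tabulate(z, k)
  first_idx <- vapply(seq_len(k), function(c) min(which(z == c)), integer(1))
  ord <- order(-sizes, first_idx)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  stats::setNames(as.integer(remap[z]), rownames(X))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
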