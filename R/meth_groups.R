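#' Discover DNA methylation groups in a WGBS cohort
#'
#' The central fitting function: selects high-variance CpG features,
#' evaluates cluster-number stability by consensus k-means (CDF area and
#' relative delta-area over a k range) and by the gap statistic against a
#' Monte-Carlo uniform reference, chooses the number of groups, assigns
#' each sample to a group, and computes Ward hierarchical clustering and a
#' 2-D embedding for visualization.
#'
#' @param cohort a \code{MethylationCohort} (see [generate_methylomes()] or
#'   [read_cohort_dir()]), or a pre-built samples x features matrix.
#' @param k_range candidate numbers of groups for the consensus analysis
#'   (default 2:6); the gap statistic additionally evaluates k = 1.
#' @param n_top number of top-variance CpG features (default 5000).
#' @param H consensus resamples (default 100).
#' @param p consensus subsample fraction (default 0.8).
#' @param B gap-statistic reference datasets (default 50).
#' @param k optional fixed number of groups, bypassing selection.
#' @param embed_method embedding for visualization (default \code{"pca"}).
#' @param seed master seed for the stochastic stages.
#' @param n_restarts k-means restarts within resamples (default 20).
#' @return an object of class \code{meth_groups}: list with \code{labels},
#'   \code{k}, \code{selection} (the [select_k()] result), \code{consensus},
#'   \code{gap}, \code{cdf} (per-k area/delta table), \code{hierarchy},
#'   \code{embedding}, \code{features} and the call.
#' @examples
#' sim <- generate_cohort(synthetic_config(n_samples = 12, n_cpgs = 2000,
#'                                         n_islands = 40,
#'                                         blocks_per_group = 10,
#'                                         hmr_group_blocks = 20,
#'                                         n_genes = 1000,
#'                                         de_genes_per_group = 60), seed = 1)
#' fit <- meth_groups(sim$cohort, k_range = 2:4, H = 20, B = 10, seed = 1)
#' fit
#' adjusted_rand_index(fit$labels, sim$truth$labels)
#' @export
meth_groups <- function(cohort, k_range = 2:6, n_top = 5000, H = 100,
                        p = 0.8, B = 50, k = NULL,
                        embed_method = c("pca", "umap", "tsne"),
                        seed = NULL, n_restarts = 20) {
  embed_method <- match.arg(embed_method)
  X <- if (inherits(cohort, "MethylationCohort"))
    select_features(cohort, n_top = n_top) else as.matrix(cohort)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  cons <- consensus_cluster(X, k_range = k_range, H = H, p = p,
                            seed = seed + 1L, n_restarts = n_restarts)
  cdf <- cdf_area(cons)
  gap <- gap_statistic(X, k_range = c(1L, k_range), B = B,
                       seed = seed + 2L, n_restarts = n_restarts)
  selection <- select_k(cdf, gap)
  k_final <- if (is.null(k)) selection$k else k
  labels <- assign_groups(X, k_final, seed = seed + 3L, n_restarts = 50)
  hier <- hierarchical_cluster(X, k_final)
  emb <- embed_samples(X, method = embed_method, seed = seed + 4L)
  structure(list(labels = labels, k = k_final, selection = selection,
                 consensus = cons, gap = gap, cdf = cdf, hierarchy = hier,
                 embedding = emb, features = X, seed = seed,
                 call = match.call()),
            class = "meth_groups")
}

#' @export
print.meth_groups <- function(x, ...) {
  cat(sprintf("Methylation group discovery: %d samples, %d CpG features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  selected k = %d (gap statistic; delta-area k = %d, %s)\n",
              x$k, x$selection$k_delta,
              if (x$selection$concordant) "concordant" else "discordant"))
  sizes <- table(x$labels)
  cat("  group sizes:", paste(sprintf("%s: %d", names(sizes), sizes),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.meth_groups <- function(object, ...) {
  out <- list(k = object$k, selection = object$selection,
              sizes = table(object$labels),
              diagnostics = object$selection$diagnostics)
  class(out) <- "summary.meth_groups"
  out
}

#' @export
print.summary.meth_groups <- function(x, ...) {
  cat(sprintf("Selected number of methylation groups: %d\n", x$k))
  cat(sprintf("  gap statistic: k = %d (unrestricted k = %d)\n",
              x$selection$k_gap, x$selection$k_gap_unrestricted))
  cat(sprintf("  consensus delta-area elbow: k = %d (threshold %.2f)\n",
              x$selection$k_delta, x$selection$delta_threshold))
  cat("\nPer-k diagnostics (consensus CDF area/delta, dispersion, gap):\n")
  print(x$diagnostics, row.names = FALSE, digits = 4)
  cat("\nGroup sizes:\n")
  print(x$sizes)
  invisible(x)
}

#' Extract group labels from a meth_groups fit
#' @param object a \code{meth_groups} object.
#' @param ... unused.
#' @return named integer vector of group labels.
#' @export
labels.meth_groups <- function(object, ...) object$labels

#' Diagnostic plots for a meth_groups fit
#'
#' Four base-graphics panels: consensus CDF curves per k, relative
#' delta-area, the gap curve with one-standard-error bars, and the 2-D
#' embedding colored by group.
#'
#' @param x a \code{meth_groups} object.
#' @param which subset of panels (1:4).
#' @param ... passed to plotting functions.
#' @export
plot.meth_groups <- function(x, which = 1:4, ...) {
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    ks <- x$consensus$k_range
    cols <- grDevices::hcl.colors(length(ks), "Dark 3")
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "consensus index",
         ylab = "CDF", main = "Consensus CDF")
    for (i in seq_along(ks)) {
      v <- x$consensus$consensus[[i]]
      v <- sort(v[upper.tri(v)])
      graphics::lines(stats::ecdf(v), col = cols[i], do.points = FALSE)
    }
    graphics::legend("bottomright", legend = paste0("k=", ks), col = cols,
                     lty = 1, bty = "n")
  }
  if (2 %in% which)
    plot(x$cdf$k, x$cdf$delta, type = "b", xlab = "k",
         ylab = "relative delta area", main = "Delta area")
  if (3 %in% which) {
    plot(x$gap$k_range, x$gap$gap, type = "b", xlab = "k", ylab = "Gap(k)",
         main = "Gap statistic")
    graphics::arrows(x$gap$k_range, x$gap$gap - x$gap$s, x$gap$k_range,
                     x$gap$gap + x$gap$s, angle = 90, code = 3,
                     length = 0.03)
  }
  if (4 %in% which)
    plot(x$embedding, col = x$labels, pch = 19, main = "Embedding")
  invisible(x)
}
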