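#' Transcripts-per-million normalization
#'
#' \code{tpm_g = 1e6 (count_g / length_g) / sum_g'(count_g' / length_g')}
#' per sample; every column sums to one million.
#'
#' @param counts gene x sample count matrix (non-negative).
#' @param lengths gene lengths in bp, named or in row order.
#' @return TPM matrix of the same shape.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive for every gene")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample with all-zero counts: ",
                          colnames(counts)[which(tot == 0)[1]])
  sweep(rate, 2, tot / 1e6, "/")
}

# vectorized two-sided Welch t over matrix rows, group vs rest
.welch_rows <- function(Y, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  y1 <- Y[, in_group, drop = FALSE]; y2 <- Y[, !in_group, drop = FALSE]
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  v1 <- rowSums((y1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((y2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: both sides constant
  zero <- se2 == 0
  t[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf * sign(m1 - m2)[zero])
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  list(mean_group = m1, mean_rest = m2, t = t, df = df, p = p)
}

#' One-vs-rest differential expression for one group
#'
#' Works on \code{log2(TPM + 1)}: the log2 fold change is the difference of
#' group means on that scale, the p-value a two-sided Welch t test per
#' gene, and q the Benjamini-Hochberg adjustment across genes. A gene is
#' flagged significant when \code{|log2FC| > lfc_threshold} and
#' \code{p < p_threshold} (raw p, mirroring the volcano convention);
#' q is reported alongside.
#'
#' @param tpm_mat TPM matrix (gene x sample).
#' @param labels group labels, one per sample (column order).
#' @param group the group compared against all remaining samples.
#' @param lfc_threshold,p_threshold significance thresholds (defaults 1 and
#'   0.05).
#' @return data.frame \code{gene_id, group, mean_group, mean_rest, log2fc,
#'   t, p, q, significant}, in gene order.
#' @export
differential_expression <- function(tpm_mat, labels, group,
                                    lfc_threshold = 1, p_threshold = 0.05) {
  if (!group %in% labels) stop("group not present in labels")
  in_group <- labels == group
  if (sum(in_group) < 2 || sum(!in_group) < 2)
    stop("both sides need at least 2 samples")
  Y <- log2(as.matrix(tpm_mat) + 1)
  w <- .welch_rows(Y, in_group)
  lfc <- w$mean_group - w$mean_rest
  q <- stats::p.adjust(w$p, method = "BH")
  data.frame(gene_id = rownames(tpm_mat), group = group,
             mean_group = w$mean_group, mean_rest = w$mean_rest,
             log2fc = lfc, t = w$t, p = w$p, q = q,
             significant = abs(lfc) > lfc_threshold & w$p < p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-vs-rest differential expression for every group
#' @inheritParams differential_expression
#' @return row-bound [differential_expression()] tables over all groups.
#' @export
differential_expression_all <- function(tpm_mat, labels,
                                        lfc_threshold = 1,
                                        p_threshold = 0.05) {
  do.call(rbind, lapply(sort(unique(labels)), function(g)
    differential_expression(tpm_mat, labels, g, lfc_threshold, p_threshold)))
}

#' Hypergeometric gene-set over-representation test
#'
#' For each set, the one-sided over-representation p-value
#' \code{P(X >= overlap)} of the hypergeometric distribution with universe
#' size N, set size K and query size n; q is Benjamini-Hochberg across
#' sets. Sets are intersected with the universe first.
#'
#' @param query character vector of genes of interest (must lie in the
#'   universe); an empty query yields p = 1 for every set.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param universe the background gene list (non-empty).
#' @return data.frame \code{set, overlap, set_size, universe_size,
#'   query_size, odds_ratio, p, q}.
#' @export
enrich <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    o <- length(intersect(query, set))
    p <- if (n == 0 || K == 0) 1
         else stats::phyper(o - 1, K, N - K, n, lower.tail = FALSE)
    or <- (o * (N - K - n + o)) / ((n - o) * (K - o))
    data.frame(set = nm, overlap = o, set_size = K, universe_size = N,
               query_size = n, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Classify DE results for a volcano plot
#'
#' \code{enriched} when \code{log2FC > lfc_threshold} and
#' \code{p < p_threshold}; \code{suppressed} when
#' \code{log2FC < -lfc_threshold} and \code{p < p_threshold}; otherwise
#' \code{ns}.
#'
#' @param de a [differential_expression()] table.
#' @param lfc_threshold,p_threshold thresholds (defaults 1 and 0.05).
#' @return data.frame \code{gene_id, group, log2fc, neg_log10_p, class}.
#' @export
volcano_table <- function(de, lfc_threshold = 1, p_threshold = 0.05) {
  class <- ifelse(de$log2fc > lfc_threshold & de$p < p_threshold,
                  "enriched",
                  ifelse(de$log2fc < -lfc_threshold & de$p < p_threshold,
                         "suppressed", "ns"))
  data.frame(gene_id = de$gene_id, group = de$group, log2fc = de$log2fc,
             neg_log10_p = -log10(de$p), class = class,
             stringsAsFactors = FALSE)
}
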