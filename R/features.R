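#' Build the CpG island / shore / shelf / open-sea context track
#'
#' Shores are the +/- 2 kb flanks of islands and shelves the next +/- 2 kb
#' (i.e. 2-4 kb from the island edge). Overlaps are resolved by precedence:
#' a base overlapping any island is island, else shore, else shelf; the
#' remainder is open sea. Intervals are clipped to chromosome bounds, and
#' the resulting track partitions every chromosome.
#'
#' @param islands data.frame with \code{chrom, start, end} (0-based
#'   half-open), sorted.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param shore_bp,shelf_bp flank widths (default 2000 each).
#' @return a \code{ContextTrack}: data.frame \code{chrom, start, end,
#'   context} partitioning each chromosome, with the chromosome lengths as
#'   an attribute.
#' @export
build_context_track <- function(islands, chrom_lengths, shore_bp = 2000,
                                shelf_bp = 2000) {
  if (nrow(islands)) {
    unknown <- !islands$chrom %in% names(chrom_lengths)
    if (any(unknown)) stop("island on chromosome without a length: ",
                           islands$chrom[which(unknown)[1]])
    len <- chrom_lengths[islands$chrom]
    if (any(islands$start < 0 | islands$end > len))
      stop("island outside chromosome bounds")
  }
  ctx_levels <- c("open_sea", "shelf", "shore", "island")
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (!nrow(isl))
      return(data.frame(chrom = ch, start = 0, end = L,
                        context = "open_sea", stringsAsFactors = FALSE))
    clip <- function(s, e) {
      s <- pmax(s, 0); e <- pmin(e, L)
      keep <- s < e
      cbind(s[keep], e[keep])
    }
    tiers <- list(
      island = clip(isl$start, isl$end),
      shore = clip(c(isl$start - shore_bp, isl$end),
                   c(isl$start, isl$end + shore_bp)),
      shelf = clip(c(isl$start - shore_bp - shelf_bp,
                     isl$end + shore_bp),
                   c(isl$start - shore_bp,
                     isl$end + shore_bp + shelf_bp)))
    pts <- sort(unique(c(0, L, unlist(lapply(tiers, as.vector)))))
    pts <- pts[pts >= 0 & pts <= L]
    seg_s <- pts[-length(pts)]
    seg_e <- pts[-1]
    lab <- rep(1L, length(seg_s))  # open_sea
    for (pri in c("shelf", "shore", "island")) {
      iv <- tiers[[pri]]
      code <- match(pri, ctx_levels)
      for (r in seq_len(nrow(iv))) {
        hit <- seg_s >= iv[r, 1] & seg_e <= iv[r, 2]
        lab[hit] <- pmax(lab[hit], code)
      }
    }
    # merge adjacent segments with equal labels
    grp <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
    data.frame(chrom = ch,
               start = tapply(seg_s, grp, min),
               end = tapply(seg_e, grp, max),
               context = ctx_levels[lab[!duplicated(grp)]],
               stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  attr(track, "chrom_lengths") <- chrom_lengths
  class(track) <- c("ContextTrack", "data.frame")
  track
}

#' Call hypomethylated regions (HMRs) in one sample
#'
#' A site is hypomethylated if its beta value is below \code{tau} and its
#' coverage at least \code{min_cov}. Maximal runs of hypomethylated sites
#' whose successive positions are at most \code{max_gap} bp apart (within a
#' chromosome) form candidate regions; candidates with at least
#' \code{min_cpgs} sites are kept. Segment bounds span the first to last
#' member site; \code{mean_beta} is the unweighted mean over member sites.
#'
#' @param meth per-sample site table with columns \code{chrom, start, beta,
#'   n_total}, sorted by \code{(chrom, start)}.
#' @param tau hypomethylation threshold on beta (default 0.3).
#' @param max_gap maximum gap between successive member sites, bp.
#' @param min_cpgs minimum member sites per region.
#' @param min_cov minimum coverage for a site to be eligible.
#' @param sample_id optional id attached to the output rows.
#' @return data.frame \code{chrom, start, end, n_cpgs, mean_beta}
#'   (plus \code{sample_id} when given), non-overlapping and sorted.
#' @export
call_hmrs <- function(meth, tau = 0.3, max_gap = 500, min_cpgs = 4,
                      min_cov = 5, sample_id = NULL) {
  if (!identical(order(meth$chrom, meth$start), seq_len(nrow(meth))))
    stop("sites must be sorted by (chrom, start)")
  hypo <- !is.na(meth$beta) & meth$beta < tau & meth$n_total >= min_cov
  h <- meth[hypo, , drop = FALSE]
  if (!nrow(h)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_cpgs = integer(0),
                      mean_beta = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(sample_id)) out$sample_id <- character(0)
    return(out)
  }
  new_run <- c(TRUE, h$chrom[-1] != h$chrom[-nrow(h)] |
                 diff(h$start) > max_gap)
  run <- cumsum(new_run)
  n_cpgs <- as.integer(tabulate(run))
  keep <- n_cpgs >= min_cpgs
  first <- which(new_run)
  last <- c(first[-1] - 1L, nrow(h))
  out <- data.frame(chrom = h$chrom[first][keep],
                    start = h$start[first][keep],
                    end = h$start[last][keep] + 1,
                    n_cpgs = n_cpgs[keep],
                    mean_beta = as.numeric(tapply(h$beta, run, mean))[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

#' Call HMRs for every sample of a cohort
#'
#' @param cohort a \code{MethylationCohort}.
#' @inheritParams call_hmrs
#' @return one data.frame with a \code{sample_id} column.
#' @export
call_hmrs_cohort <- function(cohort, tau = 0.3, max_gap = 500,
                             min_cpgs = 4, min_cov = 5) {
  res <- lapply(seq_along(cohort$sample_ids), function(s) {
    meth <- data.frame(chrom = cohort$sites$chrom,
                       start = cohort$sites$start,
                       beta = cohort$beta[, s],
                       n_total = cohort$n_total[, s],
                       stringsAsFactors = FALSE)
    call_hmrs(meth, tau, max_gap, min_cpgs, min_cov,
              sample_id = cohort$sample_ids[s])
  })
  do.call(rbind, res)
}

# overlap length of query intervals with each row of a sorted track
# restricted to one chromosome; track must partition the chromosome.
.context_overlap <- function(start, end, track) {
  labs <- c("island", "shore", "shelf", "open_sea")
  ov <- matrix(0, length(start), 4, dimnames = list(NULL, labs))
  ts <- track$start; te <- track$end
  i0 <- findInterval(start, ts)
  i1 <- findInterval(end - 1, ts)
  for (q in seq_along(start)) {
    for (j in i0[q]:i1[q]) {
      w <- min(te[j], end[q]) - max(ts[j], start[q])
      if (w > 0) ov[q, track$context[j]] <- ov[q, track$context[j]] + w
    }
  }
  ov
}

# any-overlap test of queries against a set of intervals (one chromosome,
# sorted by start); uses a cumulative-max of ends.
.any_overlap_1chr <- function(qs, qe, ivs, ive) {
  if (!length(ivs)) return(rep(FALSE, length(qs)))
  ord <- order(ivs)
  ivs <- ivs[ord]; ive <- cummax(ive[ord])
  idx <- findInterval(qe - 1e-9, ivs)  # last interval with start < qe
  idx[qe <= ivs[1]] <- 0
  out <- idx > 0
  out[out] <- ive[idx[out]] > qs[out]
  out
}

.any_overlap <- function(chrom, start, end, iv) {
  out <- rep(FALSE, length(start))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    out[sel] <- .any_overlap_1chr(start[sel], end[sel], sub$start, sub$end)
  }
  out
}

#' Annotate HMRs with CpG context and genomic element
#'
#' The context label is the context class with the maximal base overlap
#' (ties resolved by precedence island > shore > shelf > open sea). The
#' element label uses any-overlap precedence promoter > exon > intron >
#' intergenic, with the promoter defined as \code{[TSS - promoter_up,
#' TSS + promoter_down)} on the gene's strand and intron meaning the
#' non-exonic gene body. The summary reports, per sample, the number of
#' HMRs, the fraction whose assigned context is island or shore, an
#' any-overlap variant of that fraction, and element counts.
#'
#' @param hmrs HMR table from [call_hmrs_cohort()] (needs
#'   \code{sample_id}); an empty table yields an empty summary.
#' @param context_track a \code{ContextTrack}.
#' @param genes optional gene track (\code{chrom, start, end, name,
#'   strand}).
#' @param exons optional exon track (\code{chrom, start, end}).
#' @param promoter_up,promoter_down promoter extent around the TSS (bp).
#' @return list with \code{hmrs} (annotated, extra columns \code{context,
#'   island_or_shore_any, element}) and \code{summary} (per sample).
#' @export
annotate_hmrs <- function(hmrs, context_track, genes = NULL, exons = NULL,
                          promoter_up = 2000, promoter_down = 500) {
  if (!nrow(hmrs)) {
    return(list(hmrs = hmrs,
                summary = data.frame(sample_id = character(0),
                                     n_hmrs = integer(0),
                                     frac_island_or_shore = numeric(0),
                                     frac_island_or_shore_any = numeric(0),
                                     n_promoter = integer(0),
                                     n_exon = integer(0),
                                     n_intron = integer(0),
                                     n_intergenic = integer(0))))
  }
  labs <- c("island", "shore", "shelf", "open_sea")
  context <- character(nrow(hmrs))
  any_is <- logical(nrow(hmrs))
  for (ch in unique(hmrs$chrom)) {
    sel <- which(hmrs$chrom == ch)
    tr <- context_track[context_track$chrom == ch, , drop = FALSE]
    if (!nrow(tr)) { context[sel] <- "open_sea"; next }
    ov <- .context_overlap(hmrs$start[sel], hmrs$end[sel], tr)
    context[sel] <- labs[max.col(ov, ties.method = "first")]
    any_is[sel] <- ov[, "island"] + ov[, "shore"] > 0
  }
  element <- rep("intergenic", nrow(hmrs))
  if (!is.null(genes) && nrow(genes)) {
    strand <- if ("strand" %in% names(genes)) genes$strand
              else rep("+", nrow(genes))
    tss <- ifelse(strand == "-", genes$end - 1, genes$start)
    prom <- data.frame(chrom = genes$chrom,
                       start = ifelse(strand == "-",
                                      tss - promoter_down + 1,
                                      tss - promoter_up),
                       end = ifelse(strand == "-",
                                    tss + promoter_up + 1,
                                    tss + promoter_down),
                       stringsAsFactors = FALSE)
    prom$start <- pmax(prom$start, 0)
    in_gene <- .any_overlap(hmrs$chrom, hmrs$start, hmrs$end, genes)
    element[in_gene] <- "intron"
    if (!is.null(exons) && nrow(exons)) {
      in_exon <- .any_overlap(hmrs$chrom, hmrs$start, hmrs$end, exons)
      element[in_exon] <- "exon"
    } else {
      element[in_gene] <- "exon"  # no exon model: gene body counts as exon
    }
    in_prom <- .any_overlap(hmrs$chrom, hmrs$start, hmrs$end, prom)
    element[in_prom] <- "promoter"
  }
  out <- hmrs
  out$context <- context
  out$island_or_shore_any <- any_is
  out$element <- element
  sample_col <- if ("sample_id" %in% names(out)) out$sample_id
                else rep("sample", nrow(out))
  summ <- do.call(rbind, lapply(unique(sample_col), function(s) {
    sub <- out[sample_col == s, , drop = FALSE]
    data.frame(sample_id = s, n_hmrs = nrow(sub),
               frac_island_or_shore =
                 mean(sub$context %in% c("island", "shore")),
               frac_island_or_shore_any = mean(sub$island_or_shore_any),
               n_promoter = sum(sub$element == "promoter"),
               n_exon = sum(sub$element == "exon"),
               n_intron = sum(sub$element == "intron"),
               n_intergenic = sum(sub$element == "intergenic"),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(hmrs = out, summary = summ)
}

# Welch's t between two vectors of bin values; infinite when one side is
# constant and the means differ, zero when both constant and equal.
.welch_t <- function(a, b) {
  m <- mean(a) - mean(b)
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  if (se2 == 0) return(if (m == 0) 0 else Inf)
  abs(m) / sqrt(se2)
}

# recursive binary segmentation of a log2-ratio vector
.segment_bins <- function(l, t_threshold, min_bins) {
  n <- length(l)
  if (n < 2 * min_bins) return(list(c(1L, n)))
  best_t <- -Inf; best_s <- NA_integer_
  for (s in min_bins:(n - min_bins)) {
    tt <- .welch_t(l[1:s], l[(s + 1):n])
    if (tt > best_t) { best_t <- tt; best_s <- s }
  }
  if (best_t > t_threshold) {
    left <- .segment_bins(l[1:best_s], t_threshold, min_bins)
    right <- .segment_bins(l[(best_s + 1):length(l)], t_threshold, min_bins)
    right <- lapply(right, function(r) r + best_s)
    return(c(left, right))
  }
  list(c(1L, n))
}

#' Call copy-number segments from binned sequencing coverage
#'
#' Per-sample coverage is summed over fixed genomic bins (all reads count,
#' including sites masked for methylation), normalized within the sample by
#' its median bin coverage and across the cohort by the per-bin median of
#' those ratios, giving a log2 ratio per bin. Each sample's chromosomes are
#' then segmented by recursive binary splitting: the split maximizing
#' Welch's |t| between left and right bin means is accepted when it exceeds
#' \code{t_threshold} with at least \code{min_bins} bins on each side.
#' Segments are called gain/loss when their mean log2 ratio exceeds
#' \code{+/- call_cutoff}.
#'
#' @param cohort a \code{MethylationCohort} with at least 3 samples.
#' @param bin_size genomic bin width, bp (default 500 kb).
#' @param t_threshold Welch |t| needed to accept a split (default 4);
#'   \code{Inf} yields one segment per chromosome.
#' @param min_bins minimum bins per segment side (default 5).
#' @param call_cutoff absolute mean log2 ratio for a gain/loss call.
#' @return data.frame \code{sample_id, chrom, start, end, n_bins,
#'   mean_log2_ratio, call}; segments tile each chromosome per sample.
#' @export
call_cnvs <- function(cohort, bin_size = 5e5, t_threshold = 4,
                      min_bins = 5, call_cutoff = 0.3) {
  if (length(cohort$sample_ids) < 3)
    stop("need at least 3 samples for the cohort median")
  if (min_bins < 2) stop("min_bins must be >= 2")
  chroms <- names(cohort$chrom_lengths)
  bin_of <- integer(nrow(cohort$sites))
  bin_tab <- do.call(rbind, lapply(chroms, function(ch) {
    L <- cohort$chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, L), stringsAsFactors = FALSE)
  }))
  key <- paste(bin_tab$chrom, bin_tab$start)
  site_bin <- paste(cohort$sites$chrom,
                    floor(cohort$sites$start / bin_size) * bin_size)
  bin_idx <- match(site_bin, key)
  cov <- rowsum(cohort$n_total, bin_idx)
  full <- matrix(0, nrow(bin_tab), ncol(cov),
                 dimnames = list(NULL, cohort$sample_ids))
  full[as.integer(rownames(cov)), ] <- cov
  cov <- pmax(full, 0.5)  # floor so empty bins stay finite in log space
  r <- sweep(cov, 2, apply(cov, 2, stats::median), "/")
  med <- apply(r, 1, stats::median)
  masked <- !is.finite(med) | med <= 0
  if (any(masked))
    warning(sum(masked), " bin(s) with zero cohort median masked")
  l <- log2(sweep(r, 1, pmax(med, .Machine$double.eps), "/"))

  res <- list()
  for (s in seq_along(cohort$sample_ids)) {
    for (ch in chroms) {
      rows <- which(bin_tab$chrom == ch & !masked)
      if (!length(rows)) next
      lv <- l[rows, s]
      segs <- .segment_bins(lv, t_threshold, min_bins)
      L <- cohort$chrom_lengths[[ch]]
      n_seg <- length(segs)
      for (si in seq_len(n_seg)) {
        i <- segs[[si]][1]; j <- segs[[si]][2]
        seg_start <- if (si == 1) 0 else bin_tab$start[rows[i]]
        seg_end <- if (si == n_seg) L else bin_tab$start[rows[j + 1]]
        m <- mean(lv[i:j])
        res[[length(res) + 1]] <- data.frame(
          sample_id = cohort$sample_ids[s], chrom = ch,
          start = seg_start, end = seg_end, n_bins = j - i + 1L,
          mean_log2_ratio = m,
          call = if (m >= call_cutoff) "gain"
                 else if (m <= -call_cutoff) "loss" else "neutral",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of the genome affected by copy-number calls
#'
#' @param segments CNV segment table from [call_cnvs()].
#' @param chrom_lengths named chromosome lengths (bp).
#' @return named numeric vector: per sample, total gain/loss length divided
#'   by total genome length.
#' @export
genome_fraction_cnv <- function(segments, chrom_lengths) {
  total <- sum(chrom_lengths)
  ids <- if ("sample_id" %in% names(segments)) unique(segments$sample_id)
         else "sample"
  out <- vapply(ids, function(s) {
    sub <- if ("sample_id" %in% names(segments))
      segments[segments$sample_id == s, , drop = FALSE] else segments
    for (ch in unique(sub$chrom)) {
      cc <- sub[sub$chrom == ch, , drop = FALSE]
      cc <- cc[order(cc$start), , drop = FALSE]
      if (nrow(cc) > 1 && any(cc$start[-1] < cc$end[-nrow(cc)]))
        stop("overlapping CNV segments for sample ", s, " on ", ch)
    }
    aff <- sub$call != "neutral"
    sum(sub$end[aff] - sub$start[aff]) / total
  }, numeric(1))
  stats::setNames(out, ids)
}
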