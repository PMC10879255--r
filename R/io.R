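#' Read a per-sample CpG methylation coverage file
#'
#' Parses the 6-column per-CpG methylation tables produced by WGBS
#' methylation extractors: \code{chrom, start, end, percent_methylation,
#' count_methylated, count_unmethylated}. Two coordinate dialects are
#' accepted: \code{"bismark"} (1-based start, as written by
#' \code{bismark2bedGraph}'s coverage output) and \code{"bedgraph"}
#' (0-based half-open). Internally everything is 0-based half-open and each
#' CpG occupies a single base (\code{end = start + 1}).
#'
#' The methylation fraction (beta value) is recomputed from the counts,
#' \code{beta = n_meth / n_total}, so that it is exact rather than limited to
#' the printed percentage precision; the percentage column is used for
#' validation only.
#'
#' @param path path to a tab-separated coverage file.
#' @param min_coverage sites with total count below this are flagged
#'   \code{masked}: they are excluded from methylation feature matrices but
#'   retained because their reads still inform copy-number binning.
#' @param format coordinate dialect of the input, see Details.
#' @return a \code{data.frame} with columns \code{chrom, start, end, beta,
#'   n_meth, n_total, masked}, sorted by \code{(chrom, start)}.
#' @export
read_methylation_coverage <- function(path, min_coverage = 5,
                                      format = c("bismark", "bedgraph")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric", "numeric", "numeric"),
                           col.names = c("chrom", "start", "end", "pct",
                                         "n_meth", "n_unmeth"),
                           quote = "", comment.char = "")
  n <- nrow(raw)
  bad_line <- function(i, why) {
    stop(sprintf("malformed coverage row at line %d of %s: %s",
                 i, path, why), call. = FALSE)
  }
  ok_counts <- is.finite(raw$n_meth) & is.finite(raw$n_unmeth) &
    raw$n_meth >= 0 & raw$n_unmeth >= 0 &
    raw$n_meth == round(raw$n_meth) & raw$n_unmeth == round(raw$n_unmeth)
  if (any(!ok_counts)) bad_line(which(!ok_counts)[1], "counts must be non-negative integers")
  ok_pct <- is.finite(raw$pct) & raw$pct >= 0 & raw$pct <= 100
  if (any(!ok_pct)) bad_line(which(!ok_pct)[1], "percentage outside [0, 100]")
  n_total <- raw$n_meth + raw$n_unmeth
  zero_bad <- n_total == 0 & raw$pct != 0
  if (any(zero_bad)) bad_line(which(zero_bad)[1], "zero counts with nonzero percentage")
  beta <- ifelse(n_total > 0, raw$n_meth / n_total, 0)
  incons <- n_total > 0 & abs(raw$pct / 100 - beta) > 0.01
  if (any(incons)) bad_line(which(incons)[1], "percentage inconsistent with counts")

  start0 <- if (format == "bismark") raw$start - 1 else raw$start
  if (any(start0 < 0)) bad_line(which(start0 < 0)[1], "negative position")
  out <- data.frame(chrom = raw$chrom, start = start0, end = start0 + 1,
                    beta = beta, n_meth = raw$n_meth, n_total = n_total,
                    masked = n_total < min_coverage,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a methylation coverage file
#'
#' Inverse of [read_methylation_coverage()]; percentages are written at fixed
#' precision but counts carry the full information, so a read/write round
#' trip is exact.
#'
#' @param meth data.frame as returned by [read_methylation_coverage()].
#' @param path output path.
#' @param format coordinate dialect to emit.
#' @export
write_methylation_coverage <- function(meth, path,
                                       format = c("bismark", "bedgraph")) {
  format <- match.arg(format)
  start_out <- if (format == "bismark") meth$start + 1 else meth$start
  end_out <- if (format == "bismark") meth$start + 1 else meth$end
  pct <- ifelse(meth$n_total > 0, 100 * meth$n_meth / meth$n_total, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   meth$chrom, as.integer(start_out), as.integer(end_out),
                   formatC(pct, format = "f", digits = 6),
                   as.integer(meth$n_meth),
                   as.integer(meth$n_total - meth$n_meth))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED interval file
#'
#' Standard BED convention: 0-based half-open, at least three tab-separated
#' columns; optional name, score and strand columns are kept when present.
#' Chromosome names are free text (no genome registry is required).
#'
#' @param path path to a BED file.
#' @return data.frame with columns \code{chrom, start, end} and, when
#'   present, \code{name, score, strand}, sorted by \code{(chrom, start)}.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED file must have at least 3 columns: ", path)
  names(raw)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(raw) > 3) {
    k <- min(ncol(raw) - 3, 3)
    names(raw)[4:(3 + k)] <- extra[seq_len(k)]
    raw <- raw[, 1:(3 + k), drop = FALSE]
  }
  if (!is.numeric(raw$start) || !is.numeric(raw$end))
    stop("BED coordinates must be numeric: ", path)
  bad <- raw$start >= raw$end
  if (any(bad))
    stop(sprintf("invalid BED interval (start >= end) at line %d of %s",
                 which(bad)[1], path))
  if (any(raw$start < 0)) stop("negative BED coordinate in ", path)
  raw <- raw[order(raw$chrom, raw$start), , drop = FALSE]
  rownames(raw) <- NULL
  raw
}

#' Write intervals as BED
#'
#' @param intervals data.frame with \code{chrom, start, end} plus any further
#'   columns, written in order after the coordinates.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-level count matrix with gene lengths
#'
#' Expects a TSV with header \code{gene_id, length_bp, <sample>...}; counts
#' must be non-negative integers and lengths positive.
#'
#' @param path path to the TSV file.
#' @return list with \code{counts} (gene x sample integer matrix, rownames =
#'   gene ids, column order as in the file) and \code{lengths} (named numeric
#'   vector of gene lengths in bp).
#' @export
read_counts <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("count table needs gene_id, length_bp and >= 1 sample column")
  if (anyDuplicated(raw[[1]]))
    stop("duplicate gene id in count table: ",
         raw[[1]][which(duplicated(raw[[1]]))[1]])
  lengths <- raw[[2]]
  if (!is.numeric(lengths) || any(lengths <= 0))
    stop("gene lengths must be positive")
  counts <- as.matrix(raw[, -(1:2), drop = FALSE])
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  rownames(counts) <- raw[[1]]
  names(lengths) <- raw[[1]]
  list(counts = counts, lengths = lengths)
}

#' Write a count matrix with gene lengths
#'
#' @param counts gene x sample matrix with rownames.
#' @param lengths named vector of gene lengths (bp).
#' @param path output path.
#' @export
write_counts <- function(counts, lengths, path) {
  df <- data.frame(gene_id = rownames(counts),
                   length_bp = as.integer(lengths[rownames(counts)]),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: \code{name <TAB> description <TAB> member...}; members
#' are de-duplicated within a set.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; set descriptions are kept in the
#'   \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]))
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[which(duplicated(nm))[1]])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), nm)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with header; required columns \code{sample_id, who_grade, location,
#' breed, mitotic_index}, optional \code{group}.
#'
#' @param path path to the TSV file.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  stopifnot(file.exists(path))
  md <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  req <- c("sample_id", "who_grade", "location", "breed", "mitotic_index")
  missing <- setdiff(req, names(md))
  if (length(missing)) stop("metadata missing columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(md$who_grade %in% 1:3)) stop("who_grade must be 1, 2 or 3")
  if (any(md$mitotic_index < 0)) stop("mitotic_index must be non-negative")
  md
}

#' Write a sample metadata table
#' @param metadata data.frame as from [read_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Fixed-precision numeric formatting shared by all result writers, so that
# reruns on identical input are byte-identical.
.fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = digits))
}

.write_tsv_fixed <- function(df, path, digits = 6) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline result tables to a directory
#'
#' Emits deterministic TSV outputs with stable column order, headers and
#' fixed float precision. Recognized table names: \code{consensus_summary}
#' (per-k stability/gap diagnostics), \code{labels}, \code{hmr} (BED-like:
#' chrom, start, end, n_cpgs, mean_beta, context, element, sample_id),
#' \code{cnv} (BED-like segments), \code{de}, \code{enrichment},
#' \code{comparisons}, \code{embedding}. Unrecognized names are written as
#' generic TSVs under \code{<name>.tsv}.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    if (nm %in% c("hmr", "cnv")) {
      # BED-like: coordinates first, integer positions
      df$start <- as.integer(df$start)
      df$end <- as.integer(df$end)
    }
    .write_tsv_fixed(df, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
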