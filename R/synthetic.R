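#' Configuration for the synthetic WGBS + RNA cohort generator
#'
#' The generator emulates a tumor methylome cohort with latent molecular
#' groups: beta values that are high genome-wide and low in CpG islands,
#' group-specific planted hypomethylated blocks (one group enriched for
#' them), binomial methylation counts at Poisson sequencing depth, planted
#' copy-number segments that scale depth, negative-binomial expression with
#' planted group markers, and per-sample mitotic index and WHO grade.
#'
#' @param n_samples number of samples in the cohort.
#' @param group_proportions latent group proportions; must sum to 1. Group
#'   sizes are apportioned by largest-remainder rounding
#'   (see [apportion_groups()]).
#' @param n_chroms,chrom_length_bp genome shape: \code{n_chroms} chromosomes
#'   of \code{chrom_length_bp} bases each.
#' @param n_cpgs total number of CpG sites.
#' @param n_islands,island_width_bp number and width of CpG islands, placed
#'   on a regular grid along each chromosome.
#' @param neighborhood_bp half-width of the island neighborhood (island
#'   +/- this many bp) that receives the dense share of CpGs.
#' @param neighborhood_fraction fraction of CpGs placed inside island
#'   neighborhoods on a jittered regular grid (dense spacing, so runs of
#'   consecutive CpGs are contiguous at sub-kilobase gaps); the remainder is
#'   uniform over the genome.
#' @param beta_open_sea,beta_island shape parameters \code{c(a, b)} of the
#'   Beta distributions for baseline methylation outside/inside islands.
#' @param blocks_per_group planted hypomethylated blocks per group;
#'   \code{hmr_group} receives \code{hmr_group_blocks} instead.
#' @param hmr_group index of the HMR-enriched group.
#' @param hmr_group_blocks planted blocks for the HMR-enriched group.
#' @param block_cpgs inclusive range of block sizes, in consecutive CpGs.
#' @param block_beta Beta shape parameters for planted block methylation.
#' @param depth_mean mean Poisson sequencing depth per CpG.
#' @param min_coverage sites below this depth are masked for methylation
#'   features (their reads still count toward CNV binning).
#' @param cnv_segments list (one element per group) of data.frames with
#'   columns \code{chrom, start, end, multiplier}; depth within a segment is
#'   scaled by \code{multiplier} for samples of that group.
#' @param n_genes,nb_dispersion expression gene count and negative-binomial
#'   dispersion (variance = mu + dispersion * mu^2).
#' @param de_genes_per_group planted differentially expressed genes per
#'   group (half up, half down at \code{+/- de_log2fc}).
#' @param de_log2fc planted absolute log2 fold change.
#' @param marker_genes ids of proliferation-marker-like genes planted up in
#'   the HMR-enriched group.
#' @param marker_log2fc planted log2 fold change for the marker genes.
#' @param mitotic_index_means per-group Poisson means of the histological
#'   mitotic index.
#' @param grade_high_prob per-group probability of high grade (WHO 2-3).
#' @param seed default master seed used when the generator functions are
#'   called without one.
#' @return a validated \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_samples = 30,
                             group_proportions = c(0.40, 0.35, 0.25),
                             n_chroms = 2,
                             chrom_length_bp = 10e6,
                             n_cpgs = 20000,
                             n_islands = 200,
                             island_width_bp = 1000,
                             neighborhood_bp = 4000,
                             neighborhood_fraction = 0.6,
                             beta_open_sea = c(8, 2),
                             beta_island = c(1.5, 8),
                             blocks_per_group = 150,
                             hmr_group = 2,
                             hmr_group_blocks = 300,
                             block_cpgs = c(8, 20),
                             block_beta = c(1, 9),
                             depth_mean = 30,
                             min_coverage = 5,
                             cnv_segments = NULL,
                             n_genes = 5000,
                             nb_dispersion = 0.1,
                             de_genes_per_group = 200,
                             de_log2fc = 2,
                             marker_genes = c("MKI67L", "TOP2AL", "FOXM1L"),
                             marker_log2fc = 2.5,
                             mitotic_index_means = c(1, 6, 1),
                             grade_high_prob = c(0.15, 0.80, 0.15),
                             seed = 7) {
  k <- length(group_proportions)
  cnv_segments <- if (is.null(cnv_segments)) .default_cnv_segments(k)
                  else .normalize_cnv_segments(cnv_segments, k)
  cfg <- list(n_samples = n_samples, group_proportions = group_proportions,
              n_chroms = n_chroms, chrom_length_bp = chrom_length_bp,
              n_cpgs = n_cpgs, n_islands = n_islands,
              island_width_bp = island_width_bp,
              neighborhood_bp = neighborhood_bp,
              neighborhood_fraction = neighborhood_fraction,
              beta_open_sea = beta_open_sea, beta_island = beta_island,
              blocks_per_group = blocks_per_group, hmr_group = hmr_group,
              hmr_group_blocks = hmr_group_blocks, block_cpgs = block_cpgs,
              block_beta = block_beta, depth_mean = depth_mean,
              min_coverage = min_coverage, cnv_segments = cnv_segments,
              n_genes = n_genes, nb_dispersion = nb_dispersion,
              de_genes_per_group = de_genes_per_group, de_log2fc = de_log2fc,
              marker_genes = marker_genes, marker_log2fc = marker_log2fc,
              mitotic_index_means = mitotic_index_means,
              grade_high_prob = grade_high_prob, seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

# Accept per-group CNV segments as data.frames or as plain lists of
# records (the YAML form); an empty top-level list means no segments.
.normalize_cnv_segments <- function(x, k) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), multiplier = numeric(0))
  if (length(x) == 0) return(rep(list(empty), k))
  lapply(x, function(seg) {
    if (is.data.frame(seg)) return(seg)
    if (length(seg) == 0) return(empty)
    do.call(rbind, lapply(seg, function(r) as.data.frame(r)))
  })
}

# Default planted CNV landscape: one segment per group, spanning whole
# coverage bins, with 1.5x gains and a 0.5x loss.
.default_cnv_segments <- function(k) {
  base <- list(
    data.frame(chrom = "chr1", start = 2e6, end = 7e6, multiplier = 1.5),
    data.frame(chrom = "chr2", start = 2e6, end = 7e6, multiplier = 0.5),
    data.frame(chrom = "chr2", start = 7.5e6, end = 10e6, multiplier = 1.5))
  out <- rep(base, length.out = k)
  out[seq_len(k)]
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic cohort configuration\n")
  cat(sprintf("  %d samples in %d groups (proportions %s)\n", x$n_samples,
              length(x$group_proportions),
              paste(x$group_proportions, collapse = "/")))
  cat(sprintf("  genome: %d x %.0f bp, %d CpGs, %d islands\n", x$n_chroms,
              x$chrom_length_bp, x$n_cpgs, x$n_islands))
  cat(sprintf("  planted blocks per group: %d (group %d: %d)\n",
              x$blocks_per_group, x$hmr_group, x$hmr_group_blocks))
  cat(sprintf("  expression: %d genes, %d DE per group at |log2FC| = %g\n",
              x$n_genes, x$de_genes_per_group, x$de_log2fc))
  invisible(x)
}

#' Validate a synthetic configuration
#' @param cfg a \code{synthetic_config}.
#' @return the config, invisibly, or an error.
#' @export
validate_synthetic_config <- function(cfg) {
  k <- length(cfg$group_proportions)
  if (abs(sum(cfg$group_proportions) - 1) > 1e-8)
    stop("group_proportions must sum to 1")
  pos <- c("n_samples", "n_chroms", "chrom_length_bp", "n_cpgs", "n_islands",
           "island_width_bp", "depth_mean", "n_genes")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (cfg$hmr_group < 1 || cfg$hmr_group > k)
    stop("hmr_group must index a group")
  if (cfg$de_genes_per_group * k > cfg$n_genes)
    stop("de_genes_per_group x n_groups exceeds n_genes")
  if (length(cfg$mitotic_index_means) != k ||
      length(cfg$grade_high_prob) != k)
    stop("per-group parameter vectors must have one entry per group")
  if (length(cfg$cnv_segments) != k)
    stop("cnv_segments must have one element per group")
  for (seg in cfg$cnv_segments) {
    if (nrow(seg) && any(seg$start < 0 | seg$end > cfg$chrom_length_bp |
                         seg$start >= seg$end))
      stop("CNV segment outside chromosome bounds")
    if (nrow(seg) && !all(seg$multiplier > 0))
      stop("CNV multipliers must be positive")
  }
  # island grid must fit within chromosomes
  per_chrom <- ceiling(cfg$n_islands / cfg$n_chroms)
  if (per_chrom * cfg$island_width_bp > cfg$chrom_length_bp)
    stop("islands exceed chromosome bounds")
  invisible(cfg)
}

#' Apportion samples to groups by largest-remainder rounding
#'
#' Deterministic integer apportionment: each group gets
#' \code{floor(p * n)}; leftover units go to the groups with the largest
#' fractional remainders, ties broken in favor of the group with the smaller
#' integer part (smaller relative error), then by group index.
#'
#' @param n total count.
#' @param proportions vector summing to 1.
#' @return integer vector of group sizes summing to \code{n}.
#' @export
apportion_groups <- function(n, proportions) {
  exact <- n * proportions
  base <- floor(exact)
  rem <- exact - base
  extra <- n - sum(base)
  if (extra > 0) {
    ord <- order(-rem, base, seq_along(rem))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

# Deterministic child seeds per generator stage, derived from one master
# seed by fixed offsets.
.child_seed <- function(seed, stage) {
  offs <- c(layout = 101L, methylome = 202L, expression = 303L,
            metadata = 404L, labels = 505L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

# Genome layout: island intervals on a regular grid and CpG positions
# (dense jittered grid inside island neighborhoods, uniform elsewhere).
.generate_layout <- function(cfg, seed) {
  set.seed(.child_seed(seed, "layout"))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  per_chrom <- apportion_groups(cfg$n_islands,
                                rep(1 / cfg$n_chroms, cfg$n_chroms))
  islands <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
    m <- per_chrom[ci]
    spacing <- cfg$chrom_length_bp / m
    center <- (seq_len(m) - 0.5) * spacing
    data.frame(chrom = chroms[ci],
               start = round(center - cfg$island_width_bp / 2),
               end = round(center + cfg$island_width_bp / 2),
               stringsAsFactors = FALSE)
  }))
  if (any(islands$start < 0 | islands$end > cfg$chrom_length_bp))
    stop("islands exceed chromosome bounds")

  n_nb <- round(cfg$neighborhood_fraction * cfg$n_cpgs)
  n_windows <- nrow(islands)
  per_window <- apportion_groups(n_nb, rep(1 / n_windows, n_windows))
  w_start <- pmax(islands$start - cfg$neighborhood_bp, 0)
  w_end <- pmin(islands$end + cfg$neighborhood_bp, cfg$chrom_length_bp)
  nb <- do.call(rbind, lapply(seq_len(n_windows), function(w) {
    m <- per_window[w]
    width <- w_end[w] - w_start[w]
    step <- width / m
    pos <- w_start[w] + round((seq_len(m) - 0.5) * step) +
      round(stats::runif(m, -step * 0.27, step * 0.27))
    pos <- pmin(pmax(pos, w_start[w]), w_end[w] - 1)
    data.frame(chrom = islands$chrom[w], start = pos, window = w,
               stringsAsFactors = FALSE)
  }))
  n_unif <- cfg$n_cpgs - n_nb
  uc <- sample(seq_len(cfg$n_chroms), n_unif, replace = TRUE)
  unif <- data.frame(chrom = chroms[uc],
                     start = floor(stats::runif(n_unif, 0,
                                                cfg$chrom_length_bp)),
                     window = NA_integer_, stringsAsFactors = FALSE)
  sites <- rbind(nb, unif)
  sites <- sites[!duplicated(sites[c("chrom", "start")]), , drop = FALSE]
  # top up after de-duplication so the configured count is exact
  while (nrow(sites) < cfg$n_cpgs) {
    need <- cfg$n_cpgs - nrow(sites)
    uc <- sample(seq_len(cfg$n_chroms), need, replace = TRUE)
    more <- data.frame(chrom = chroms[uc],
                       start = floor(stats::runif(need, 0,
                                                  cfg$chrom_length_bp)),
                       window = NA_integer_, stringsAsFactors = FALSE)
    sites <- rbind(sites, more)
    sites <- sites[!duplicated(sites[c("chrom", "start")]), , drop = FALSE]
  }
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  sites$end <- sites$start + 1
  # membership in an island proper (not just its neighborhood)
  sites$in_island <- .in_intervals(sites$chrom, sites$start, islands)
  # recompute window membership on the sorted table
  sites$window <- .window_of(sites$chrom, sites$start, islands,
                             w_start, w_end)
  list(islands = islands, sites = sites,
       chrom_lengths = stats::setNames(rep(cfg$chrom_length_bp,
                                           cfg$n_chroms), chroms))
}

.in_intervals <- function(chrom, pos, iv) {
  out <- logical(length(pos))
  for (ch in unique(iv$chrom)) {
    sel <- chrom == ch
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    idx <- findInterval(pos[sel], sub$start)
    hit <- idx > 0 & pos[sel] < sub$end[pmax(idx, 1)]
    out[sel] <- hit
  }
  out
}

.window_of <- function(chrom, pos, islands, w_start, w_end) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(islands$chrom)) {
    sel <- which(chrom == ch)
    wi <- which(islands$chrom == ch)
    idx <- findInterval(pos[sel], w_start[wi])
    ok <- idx > 0 & pos[sel] < w_end[wi][pmax(idx, 1)]
    out[sel[ok]] <- wi[idx[ok]]
  }
  out
}

# Place planted blocks (runs of consecutive CpGs inside island
# neighborhoods) without overlap across groups: first-fit decreasing over
# window capacity.
.place_blocks <- function(cfg, layout) {
  k <- length(cfg$group_proportions)
  n_blocks <- ifelse(seq_len(k) == cfg$hmr_group,
                     cfg$hmr_group_blocks, cfg$blocks_per_group)
  sizes <- unlist(lapply(seq_len(k), function(g) {
    if (n_blocks[g] == 0) return(integer(0))
    sample(seq(cfg$block_cpgs[1], cfg$block_cpgs[2]), n_blocks[g],
           replace = TRUE)
  }))
  groups <- rep(seq_len(k), n_blocks)
  if (!length(sizes))
    return(data.frame(group = integer(0), first = integer(0),
                      last = integer(0)))
  ord <- order(-sizes)
  sizes <- sizes[ord]; groups <- groups[ord]
  win <- layout$sites$window
  runs <- split(which(!is.na(win)), win[!is.na(win)])
  # runs are contiguous index ranges by construction (a window is one
  # genomic interval, so its member sites are consecutive after sorting)
  stopifnot(all(vapply(runs, function(r) all(diff(r) == 1L), logical(1))))
  cursor <- vapply(runs, `[`, integer(1), 1)
  remaining <- lengths(runs)
  first <- integer(length(sizes)); last <- integer(length(sizes))
  for (b in seq_along(sizes)) {
    w <- which(remaining >= sizes[b])[1]
    if (is.na(w)) stop("unable to place planted blocks: insufficient ",
                       "dense CpG capacity for the configured block load")
    first[b] <- cursor[w]
    last[b] <- cursor[w] + sizes[b] - 1L
    cursor[w] <- cursor[w] + sizes[b]
    remaining[w] <- remaining[w] - sizes[b]
  }
  data.frame(group = groups, first = first, last = last)
}

# Per-site depth multiplier for one group's planted CNV segments.
.cnv_multiplier <- function(sites, segs) {
  mult <- rep(1, nrow(sites))
  if (is.null(segs) || !nrow(segs)) return(mult)
  for (i in seq_len(nrow(segs))) {
    hit <- sites$chrom == segs$chrom[i] & sites$start >= segs$start[i] &
      sites$start < segs$end[i]
    mult[hit] <- mult[hit] * segs$multiplier[i]
  }
  mult
}

#' Generate a synthetic WGBS cohort with planted group structure
#'
#' Draws baseline per-site methylation (high in open sea, low in islands),
#' overrides it inside each group's planted hypomethylated blocks, then
#' samples per-sample sequencing depth as Poisson (scaled by that sample's
#' planted CNV multiplier at the site) and methylated counts as Binomial.
#'
#' @param cfg a [synthetic_config()].
#' @param seed master seed (defaults to \code{cfg$seed}); the run is fully
#'   deterministic given the seed.
#' @param keep_true_beta if TRUE, the latent per-site/sample true beta
#'   matrix is kept in the truth ledger (memory permitting).
#' @return list with \code{cohort} (a \code{MethylationCohort}) and
#'   \code{truth} (a \code{TruthLedger} with planted labels, block and CNV
#'   intervals and island track).
#' @export
generate_methylomes <- function(cfg, seed = cfg$seed,
                                keep_true_beta = FALSE) {
  validate_synthetic_config(cfg)
  k <- length(cfg$group_proportions)
  sizes <- apportion_groups(cfg$n_samples, cfg$group_proportions)
  set.seed(.child_seed(seed, "labels"))
  labels <- sample(rep(seq_len(k), sizes))
  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  names(labels) <- sample_ids

  layout <- .generate_layout(cfg, seed)
  set.seed(.child_seed(seed, "methylome"))
  blocks <- .place_blocks(cfg, layout)

  ns <- nrow(layout$sites)
  baseline <- ifelse(layout$sites$in_island,
                     stats::rbeta(ns, cfg$beta_island[1], cfg$beta_island[2]),
                     stats::rbeta(ns, cfg$beta_open_sea[1],
                                  cfg$beta_open_sea[2]))
  beta_true <- matrix(baseline, nrow = ns, ncol = cfg$n_samples)
  for (b in seq_len(nrow(blocks))) {
    idx <- blocks$first[b]:blocks$last[b]
    bb <- stats::rbeta(length(idx), cfg$block_beta[1], cfg$block_beta[2])
    beta_true[idx, labels == blocks$group[b]] <- bb
  }

  mult <- vapply(seq_len(k), function(g)
    .cnv_multiplier(layout$sites, cfg$cnv_segments[[g]]), numeric(ns))
  lambda <- cfg$depth_mean * mult[, labels, drop = FALSE]
  depth <- matrix(stats::rpois(ns * cfg$n_samples, lambda), nrow = ns)
  n_meth <- matrix(stats::rbinom(ns * cfg$n_samples, depth, beta_true),
                   nrow = ns)
  beta_obs <- ifelse(depth > 0, n_meth / depth, NA_real_)
  dimnames(beta_obs) <- dimnames(n_meth) <- dimnames(depth) <-
    list(NULL, sample_ids)

  cohort <- structure(
    list(sites = layout$sites[c("chrom", "start", "end", "in_island")],
         beta = beta_obs, n_meth = n_meth, n_total = depth,
         sample_ids = sample_ids, chrom_lengths = layout$chrom_lengths,
         min_coverage = cfg$min_coverage),
    class = "MethylationCohort")

  block_iv <- data.frame(
    chrom = layout$sites$chrom[blocks$first],
    start = layout$sites$start[blocks$first],
    end = layout$sites$start[blocks$last] + 1,
    group = blocks$group, stringsAsFactors = FALSE)
  block_iv <- block_iv[order(block_iv$chrom, block_iv$start), , drop = FALSE]
  rownames(block_iv) <- NULL
  cnv_per_sample <- do.call(rbind, lapply(seq_len(cfg$n_samples), function(s) {
    seg <- cfg$cnv_segments[[labels[s]]]
    if (!nrow(seg)) return(NULL)
    cbind(sample_id = sample_ids[s], seg, stringsAsFactors = FALSE)
  }))
  truth <- structure(list(labels = labels, blocks = block_iv,
                          cnv_segments = cnv_per_sample,
                          islands = layout$islands,
                          chrom_lengths = layout$chrom_lengths),
                     class = "TruthLedger")
  if (keep_true_beta) truth$true_beta <- beta_true
  list(cohort = cohort, truth = truth)
}

#' @export
print.MethylationCohort <- function(x, ...) {
  cat(sprintf("MethylationCohort: %d CpG sites x %d samples on %d chromosome(s)\n",
              nrow(x$sites), length(x$sample_ids),
              length(unique(x$sites$chrom))))
  cat(sprintf("  median depth %.0f; %.1f%% of site/sample cells below coverage %d\n",
              stats::median(x$n_total), 100 * mean(x$n_total < x$min_coverage),
              x$min_coverage))
  invisible(x)
}

#' Gene ids, planted DE assignments and marker placement for the generator
#'
#' Deterministic (seed-free): gene ids are \code{gene_0001 ...}; each group
#' owns a fixed consecutive slice of \code{de_genes_per_group} genes (first
#' half planted up, second half down), and the proliferation-marker-like
#' genes replace the first ids of the HMR-enriched group's up slice so that
#' a packaged gene-set fixture can reference them.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame with \code{gene_id, group, log2fc} (group \code{NA}
#'   for non-DE genes).
#' @export
planted_de_genes <- function(cfg) {
  k <- length(cfg$group_proportions)
  ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  group <- rep(NA_integer_, cfg$n_genes)
  lfc <- rep(0, cfg$n_genes)
  d <- cfg$de_genes_per_group
  half <- floor(d / 2)
  for (g in seq_len(k)) {
    idx <- ((g - 1) * d + 1):(g * d)
    group[idx] <- g
    lfc[idx] <- c(rep(cfg$de_log2fc, half), rep(-cfg$de_log2fc, d - half))
  }
  mk <- cfg$marker_genes
  mpos <- (cfg$hmr_group - 1) * d + seq_along(mk)
  ids[mpos] <- mk
  lfc[mpos] <- cfg$marker_log2fc
  data.frame(gene_id = ids, group = group, log2fc = lfc,
             stringsAsFactors = FALSE)
}

#' Generate synthetic expression counts with planted group markers
#'
#' Counts are negative binomial around a per-gene baseline mean; planted DE
#' genes have their mean multiplied by \code{2^log2fc} in their group, and
#' the proliferation-marker-like genes are up-shifted in the HMR-enriched
#' group.
#'
#' @param cfg a [synthetic_config()].
#' @param labels integer group labels, one per sample.
#' @param seed master seed (defaults to \code{cfg$seed}).
#' @return list with \code{counts} (gene x sample), \code{lengths} (named,
#'   bp), and \code{truth_de} (planted DE table from [planted_de_genes()]).
#' @export
generate_expression <- function(cfg, labels, seed = cfg$seed) {
  validate_synthetic_config(cfg)
  if (length(labels) != cfg$n_samples)
    stop("labels length must equal n_samples")
  de <- planted_de_genes(cfg)
  set.seed(.child_seed(seed, "expression"))
  base_mu <- stats::rlnorm(cfg$n_genes, meanlog = log(100), sdlog = 1.2)
  lengths <- stats::setNames(sample(500:5000, cfg$n_genes, replace = TRUE),
                             de$gene_id)
  mu <- matrix(base_mu, nrow = cfg$n_genes, ncol = cfg$n_samples)
  for (g in sort(unique(de$group[!is.na(de$group)]))) {
    idx <- which(!is.na(de$group) & de$group == g)
    mu[idx, labels == g] <- mu[idx, labels == g] * 2^de$log2fc[idx]
  }
  size <- 1 / max(cfg$nb_dispersion, 1e-12)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                   nrow = cfg$n_genes,
                   dimnames = list(de$gene_id,
                                   sprintf("S%02d", seq_len(cfg$n_samples))))
  list(counts = counts, lengths = lengths,
       truth_de = de[!is.na(de$group), , drop = FALSE])
}

#' Generate synthetic sample metadata
#'
#' Mitotic index is Poisson with a per-group mean (high in the HMR-enriched
#' group); WHO grade is drawn so that the HMR-enriched group is enriched for
#' grades 2-3.
#'
#' @param cfg a [synthetic_config()].
#' @param labels integer group labels, one per sample.
#' @param seed master seed (defaults to \code{cfg$seed}).
#' @return metadata data.frame (sample_id, who_grade, location, breed,
#'   mitotic_index, group).
#' @export
generate_metadata <- function(cfg, labels, seed = cfg$seed) {
  validate_synthetic_config(cfg)
  if (length(labels) != cfg$n_samples)
    stop("labels length must equal n_samples")
  set.seed(.child_seed(seed, "metadata"))
  n <- cfg$n_samples
  mit <- stats::rpois(n, cfg$mitotic_index_means[labels])
  high <- stats::rbinom(n, 1, cfg$grade_high_prob[labels])
  grade <- ifelse(high == 1, sample(2:3, n, replace = TRUE), 1L)
  breeds <- c("Boxer", "Golden Retriever", "Labrador Retriever", "Beagle",
              "Border Collie", "German Shepherd", "Boston Terrier",
              "Australian Shepherd", "Rottweiler", "Mixed breed",
              "Miniature Schnauzer", "Doberman Pinscher")
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             who_grade = as.integer(grade),
             location = sample(c("intracranial", "spinal"), n,
                               replace = TRUE, prob = c(0.8, 0.2)),
             breed = sample(breeds, n, replace = TRUE),
             mitotic_index = mit,
             group = as.integer(labels),
             stringsAsFactors = FALSE)
}

# Simple non-overlapping gene models for element annotation: genes laid out
# in alternating-strand slots along the genome, each with 3 exons.
.generate_gene_models <- function(cfg, lengths, seed) {
  set.seed(.child_seed(seed, "layout") + 1L)
  n_genomic <- min(cfg$n_genes, 1500L)
  ids <- names(lengths)[seq_len(n_genomic)]
  per_chrom <- apportion_groups(n_genomic, rep(1 / cfg$n_chroms,
                                               cfg$n_chroms))
  genes <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
    m <- per_chrom[ci]
    slot <- cfg$chrom_length_bp / m
    i0 <- sum(per_chrom[seq_len(ci - 1)])
    gid <- ids[(i0 + 1):(i0 + m)]
    glen <- pmin(lengths[gid], floor(slot) - 1000)
    start <- round((seq_len(m) - 1) * slot) + 500
    data.frame(chrom = paste0("chr", ci), start = start,
               end = start + glen, name = gid, score = 0L,
               strand = rep(c("+", "-"), length.out = m),
               stringsAsFactors = FALSE)
  }))
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    L <- genes$end[i] - genes$start[i]
    cuts <- round(genes$start[i] + L * c(0, 0.25, 0.4, 0.65, 0.8, 1))
    data.frame(chrom = genes$chrom[i],
               start = cuts[c(1, 3, 5)], end = cuts[c(2, 4, 6)],
               name = paste0(genes$name[i], "_exon", 1:3),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  exons <- exons[order(exons$chrom, exons$start), , drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Generate the full synthetic cohort (methylomes, expression, metadata)
#'
#' @param cfg a [synthetic_config()].
#' @param seed master seed (defaults to \code{cfg$seed}); per-stage child
#'   seeds are derived by fixed offsets so individual stages reproduce the
#'   monolithic run.
#' @return list with \code{cohort}, \code{expression}, \code{metadata},
#'   \code{gene_models} and \code{truth}.
#' @export
generate_cohort <- function(cfg = synthetic_config(), seed = cfg$seed) {
  meth <- generate_methylomes(cfg, seed)
  expr <- generate_expression(cfg, meth$truth$labels, seed)
  md <- generate_metadata(cfg, meth$truth$labels, seed)
  gm <- .generate_gene_models(cfg, expr$lengths, seed)
  truth <- meth$truth
  truth$de_genes <- expr$truth_de
  list(cohort = meth$cohort, expression = expr, metadata = md,
       gene_models = gm, truth = truth, config = cfg)
}

#' Synthetic hallmark-like gene sets matching the generator's planted genes
#'
#' Deterministic gene sets over the generator's fixed gene ids: one
#' biology-flavored set per group built from that group's planted
#' up-regulated genes (the proliferation set contains the marker genes),
#' plus unrelated filler sets. The same sets ship as a packaged GMT fixture.
#'
#' @param cfg a [synthetic_config()].
#' @return named list of character vectors (see [read_gmt()]).
#' @export
make_gene_sets <- function(cfg = synthetic_config()) {
  de <- planted_de_genes(cfg)
  up <- function(g) de$gene_id[!is.na(de$group) & de$group == g &
                                 de$log2fc > 0]
  ids <- de$gene_id
  clip <- function(i) ids[i[i <= length(ids)]]
  sets <- list(
    INFLAMMATORY_RESPONSE_LIKE = up(1),
    PROLIFERATION_FOXM1_LIKE = up(cfg$hmr_group),
    HEDGEHOG_SIGNALING_LIKE = up(min(3, length(cfg$group_proportions))),
    RIBOSOME_LIKE = clip(1001:1080),
    METABOLISM_LIKE = clip(2001:2060),
    HOUSEKEEPING_LIKE = clip(3001:3100))
  sets[lengths(sets) > 0]
}

#' Write a generated cohort to disk in the pipeline's input formats
#'
#' Emits per-sample coverage files, island/gene/exon BED tracks, the count
#' matrix, metadata, gene sets (GMT) and the truth ledger (JSON), i.e. the
#' exact formats the readers in this package accept, so the pipeline can be
#' exercised end-to-end from files.
#'
#' @param sim output of [generate_cohort()].
#' @param dir output directory.
#' @param format coverage coordinate dialect to write.
#' @return invisibly, \code{dir}.
#' @export
write_cohort <- function(sim, dir, format = c("bismark", "bedgraph")) {
  format <- match.arg(format)
  dir.create(file.path(dir, "coverage"), recursive = TRUE,
             showWarnings = FALSE)
  co <- sim$cohort
  for (s in seq_along(co$sample_ids)) {
    meth <- data.frame(chrom = co$sites$chrom, start = co$sites$start,
                       end = co$sites$end,
                       n_meth = co$n_meth[, s], n_total = co$n_total[, s],
                       stringsAsFactors = FALSE)
    write_methylation_coverage(
      meth, file.path(dir, "coverage", paste0(co$sample_ids[s], ".cov")),
      format = format)
  }
  write_bed(sim$truth$islands, file.path(dir, "islands.bed"))
  write_bed(sim$gene_models$genes, file.path(dir, "genes.bed"))
  write_bed(sim$gene_models$exons, file.path(dir, "exons.bed"))
  write_counts(sim$expression$counts, sim$expression$lengths,
               file.path(dir, "counts.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  cfg_for_sets <- if (!is.null(sim$config)) sim$config else synthetic_config()
  write_gmt(make_gene_sets(cfg_for_sets), file.path(dir, "genesets.gmt"))
  writeLines(paste(names(sim$truth$chrom_lengths),
                   as.integer(sim$truth$chrom_lengths), sep = "\t"),
             file.path(dir, "chrom_lengths.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(labels = as.list(truth$labels), blocks = truth$blocks,
         cnv_segments = truth$cnv_segments, islands = truth$islands,
         de_genes = truth$de_genes,
         chrom_lengths = as.list(truth$chrom_lengths)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
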