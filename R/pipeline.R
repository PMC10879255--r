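#' Load and validate a pipeline configuration
#'
#' Configuration is a YAML file (or an equivalent named list) with blocks
#' \code{input} (\code{"synthetic"} or a data directory written by
#' [write_cohort()]), \code{synthetic} (overrides for [synthetic_config()]),
#' \code{clustering}, \code{hmr}, \code{cnv}, \code{de}, plus \code{seed}
#' and \code{out_dir}. Unknown keys are rejected.
#'
#' @param x path to a YAML file, or a named list.
#' @return validated config list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(cfg)) cfg <- list()
  defaults <- list(
    input = "synthetic",
    coverage_format = "bismark",
    seed = 7,
    out_dir = "methgroups_results",
    synthetic = list(),
    clustering = list(k_range = c(2, 6), H = 100, p = 0.8, B = 50,
                      n_top = 5000, n_restarts = 20,
                      embed_method = "pca"),
    hmr = list(tau = 0.3, max_gap = 500, min_cpgs = 4, min_cov = 5,
               promoter_up = 2000, promoter_down = 500),
    cnv = list(bin_size = 5e5, t_threshold = 4, min_bins = 5,
               call_cutoff = 0.3),
    de = list(lfc_threshold = 1, p_threshold = 0.05))
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (block in c("clustering", "hmr", "cnv", "de")) {
    bad <- setdiff(names(cfg[[block]]), names(defaults[[block]]))
    if (length(bad)) stop("unknown key(s) in '", block, "': ",
                          paste(bad, collapse = ", "))
    defaults[[block]][names(cfg[[block]])] <- cfg[[block]]
  }
  if (!is.null(cfg$synthetic)) {
    bad <- setdiff(names(cfg$synthetic), names(formals(synthetic_config)))
    if (length(bad)) stop("unknown key(s) in 'synthetic': ",
                          paste(bad, collapse = ", "))
    defaults$synthetic <- cfg$synthetic
  }
  for (key in c("input", "coverage_format", "seed", "out_dir"))
    if (!is.null(cfg[[key]])) defaults[[key]] <- cfg[[key]]
  cl <- defaults$clustering
  if (length(cl$k_range) == 2) defaults$clustering$k_range <-
      seq(cl$k_range[1], cl$k_range[2])
  with(defaults$clustering, {
    if (H < 2) stop("clustering H must be >= 2")
    if (p <= 0 || p > 1) stop("clustering p must be in (0, 1]")
    if (B < 2) stop("clustering B must be >= 2")
    if (min(k_range) < 2) stop("clustering k_range must start at >= 2")
  })
  with(defaults$hmr, {
    if (tau <= 0 || tau >= 1) stop("hmr tau must be in (0, 1)")
    if (min_cpgs < 1) stop("hmr min_cpgs must be >= 1")
  })
  with(defaults$cnv, {
    if (bin_size <= 0) stop("cnv bin_size must be positive")
    if (min_bins < 2) stop("cnv min_bins must be >= 2")
  })
  structure(defaults, class = "pipeline_config")
}

# read a cohort written by write_cohort() back into a MethylationCohort
#' Read a cohort data directory
#'
#' Reads the per-sample coverage files plus island/gene/exon tracks, counts
#' and metadata from a directory in the layout written by [write_cohort()].
#' All coverage files must share the same site coordinates.
#'
#' @param dir data directory.
#' @param min_coverage coverage threshold for masking.
#' @param format coverage coordinate dialect.
#' @return list with \code{cohort}, \code{islands}, \code{genes},
#'   \code{exons}, \code{counts}, \code{lengths}, \code{metadata},
#'   \code{gene_sets} (and \code{truth} when a truth ledger is present).
#' @export
read_cohort_dir <- function(dir, min_coverage = 5,
                            format = c("bismark", "bedgraph")) {
  format <- match.arg(format)
  cov_files <- sort(list.files(file.path(dir, "coverage"),
                               pattern = "\\.cov$", full.names = TRUE))
  if (!length(cov_files)) stop("no coverage files under ", dir,
                               "; run the simulate stage first")
  sample_ids <- sub("\\.cov$", "", basename(cov_files))
  tabs <- lapply(cov_files, read_methylation_coverage,
                 min_coverage = min_coverage, format = format)
  key <- paste(tabs[[1]]$chrom, tabs[[1]]$start)
  for (t in tabs[-1])
    if (!identical(paste(t$chrom, t$start), key))
      stop("coverage files do not share identical CpG sites")
  cl_path <- file.path(dir, "chrom_lengths.tsv")
  if (file.exists(cl_path)) {
    cl <- utils::read.table(cl_path, sep = "\t", stringsAsFactors = FALSE)
    chrom_lengths <- stats::setNames(cl[[2]], cl[[1]])
  } else {
    chrom_lengths <- tapply(tabs[[1]]$end, tabs[[1]]$chrom, max)
  }
  cohort <- structure(
    list(sites = tabs[[1]][c("chrom", "start", "end")],
         beta = do.call(cbind, lapply(tabs, function(t)
           ifelse(t$n_total > 0, t$beta, NA_real_))),
         n_meth = do.call(cbind, lapply(tabs, `[[`, "n_meth")),
         n_total = do.call(cbind, lapply(tabs, `[[`, "n_total")),
         sample_ids = sample_ids, chrom_lengths = chrom_lengths,
         min_coverage = min_coverage),
    class = "MethylationCohort")
  colnames(cohort$beta) <- colnames(cohort$n_meth) <-
    colnames(cohort$n_total) <- sample_ids
  opt <- function(path, reader) if (file.exists(path)) reader(path) else NULL
  counts <- opt(file.path(dir, "counts.tsv"), read_counts)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(cohort = cohort,
       islands = opt(file.path(dir, "islands.bed"), read_bed),
       genes = opt(file.path(dir, "genes.bed"), read_bed),
       exons = opt(file.path(dir, "exons.bed"), read_bed),
       counts = counts$counts, lengths = counts$lengths,
       metadata = opt(file.path(dir, "metadata.tsv"), read_metadata),
       gene_sets = opt(file.path(dir, "genesets.gmt"), read_gmt),
       truth = truth)
}

.stage_log <- function(stage, seed, params = list()) {
  msg <- sprintf("[%s] seed=%s %s", stage, format(seed),
                 paste(names(params), unlist(lapply(params, paste,
                                                    collapse = ",")),
                       sep = "=", collapse = " "))
  message(msg)
  invisible(msg)
}

.need_file <- function(path, producer) {
  if (!file.exists(path))
    stop("missing ", path, "; run the '", producer, "' stage first",
         call. = FALSE)
  path
}

#' Pipeline stage: simulate a synthetic cohort to disk
#' @param config a [pipeline_config()].
#' @param out_dir output directory (default from config).
#' @param seed master seed (default from config).
#' @return the data directory, invisibly.
#' @export
stage_simulate <- function(config, out_dir = config$out_dir,
                           seed = config$seed) {
  .stage_log("simulate", seed)
  scfg <- do.call(synthetic_config, config$synthetic)
  sim <- generate_cohort(scfg, seed = seed)
  write_cohort(sim, file.path(out_dir, "data"),
               format = config$coverage_format)
  invisible(file.path(out_dir, "data"))
}

#' Pipeline stage: methylation group discovery from files
#' @inheritParams stage_simulate
#' @return the [meth_groups()] fit, invisibly.
#' @export
stage_cluster <- function(config, out_dir = config$out_dir,
                          seed = config$seed) {
  cl <- config$clustering
  .stage_log("cluster", seed, cl["k_range"])
  data_dir <- if (config$input == "synthetic") file.path(out_dir, "data")
              else config$input
  dat <- read_cohort_dir(data_dir, min_coverage = config$hmr$min_cov,
                         format = config$coverage_format)
  if (max(cl$k_range) > length(dat$cohort$sample_ids))
    stop("k_range maximum exceeds the number of samples")
  fit <- meth_groups(dat$cohort, k_range = cl$k_range, n_top = cl$n_top,
                     H = cl$H, p = cl$p, B = cl$B, seed = seed,
                     embed_method = cl$embed_method,
                     n_restarts = cl$n_restarts)
  cdir <- file.path(out_dir, "cluster")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv_fixed(data.frame(sample_id = names(fit$labels),
                              group = as.integer(fit$labels)),
                   file.path(cdir, "labels.tsv"))
  .write_tsv_fixed(fit$selection$diagnostics,
                   file.path(cdir, "diagnostics.tsv"))
  .write_tsv_fixed(data.frame(sample_id = rownames(fit$embedding),
                              fit$embedding),
                   file.path(cdir, "embedding.tsv"))
  for (i in seq_along(fit$consensus$k_range)) {
    .write_tsv_fixed(as.data.frame(fit$consensus$consensus[[i]]),
                     file.path(cdir, sprintf("consensus_k%d.tsv",
                                             fit$consensus$k_range[i])))
  }
  jsonlite::write_json(list(k = fit$k, k_gap = fit$selection$k_gap,
                            k_delta = fit$selection$k_delta,
                            concordant = fit$selection$concordant),
                       file.path(cdir, "selected_k.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Pipeline stage: HMR calling and annotation from files
#' @inheritParams stage_simulate
#' @return list with the annotated HMR table and per-sample summary.
#' @export
stage_hmr <- function(config, out_dir = config$out_dir,
                      seed = config$seed) {
  hp <- config$hmr
  .stage_log("hmr", seed, hp[c("tau", "max_gap", "min_cpgs")])
  data_dir <- if (config$input == "synthetic") file.path(out_dir, "data")
              else config$input
  dat <- read_cohort_dir(data_dir, min_coverage = hp$min_cov,
                         format = config$coverage_format)
  hmrs <- call_hmrs_cohort(dat$cohort, tau = hp$tau, max_gap = hp$max_gap,
                           min_cpgs = hp$min_cpgs, min_cov = hp$min_cov)
  track <- build_context_track(dat$islands, dat$cohort$chrom_lengths)
  ann <- annotate_hmrs(hmrs, track, genes = dat$genes, exons = dat$exons,
                       promoter_up = hp$promoter_up,
                       promoter_down = hp$promoter_down)
  hdir <- file.path(out_dir, "hmr")
  dir.create(hdir, recursive = TRUE, showWarnings = FALSE)
  hm <- ann$hmrs[c("chrom", "start", "end", "n_cpgs", "mean_beta",
                   "context", "element", "sample_id")]
  write_results(list(hmr = hm, hmr_summary = ann$summary), hdir)
  invisible(ann)
}

#' Pipeline stage: CNV segmentation from files
#' @inheritParams stage_simulate
#' @return list with the segment table and per-sample genome fractions.
#' @export
stage_cnv <- function(config, out_dir = config$out_dir,
                      seed = config$seed) {
  cp <- config$cnv
  .stage_log("cnv", seed, cp["bin_size"])
  data_dir <- if (config$input == "synthetic") file.path(out_dir, "data")
              else config$input
  dat <- read_cohort_dir(data_dir, min_coverage = config$hmr$min_cov,
                         format = config$coverage_format)
  segs <- call_cnvs(dat$cohort, bin_size = cp$bin_size,
                    t_threshold = cp$t_threshold, min_bins = cp$min_bins,
                    call_cutoff = cp$call_cutoff)
  frac <- genome_fraction_cnv(segs, dat$cohort$chrom_lengths)
  cdir <- file.path(out_dir, "cnv")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  write_results(list(
    cnv = segs,
    cnv_summary = data.frame(sample_id = names(frac),
                             genome_fraction_cnv = as.numeric(frac))), cdir)
  invisible(list(segments = segs, genome_fraction = frac))
}

#' Pipeline stage: one-vs-rest differential expression from files
#' @inheritParams stage_simulate
#' @return the combined DE table, invisibly.
#' @export
stage_de <- function(config, out_dir = config$out_dir,
                     seed = config$seed) {
  dp <- config$de
  .stage_log("de", seed, dp)
  data_dir <- if (config$input == "synthetic") file.path(out_dir, "data")
              else config$input
  labels_path <- .need_file(file.path(out_dir, "cluster", "labels.tsv"),
                            "cluster")
  labels_df <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  counts <- read_counts(.need_file(file.path(data_dir, "counts.tsv"),
                                   "simulate"))
  labels <- labels_df$group[match(colnames(counts$counts),
                                  labels_df$sample_id)]
  if (any(is.na(labels))) stop("labels do not cover all expression samples")
  tp <- tpm(counts$counts, counts$lengths)
  de <- differential_expression_all(tp, labels,
                                    lfc_threshold = dp$lfc_threshold,
                                    p_threshold = dp$p_threshold)
  vol <- do.call(rbind, lapply(split(de, de$group), volcano_table,
                               lfc_threshold = dp$lfc_threshold,
                               p_threshold = dp$p_threshold))
  rownames(vol) <- NULL
  ddir <- file.path(out_dir, "de")
  dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
  write_results(list(de = de, volcano = vol), ddir)
  invisible(de)
}

#' Pipeline stage: gene-set enrichment of DE genes from files
#' @inheritParams stage_simulate
#' @return the combined enrichment table, invisibly.
#' @export
stage_enrich <- function(config, out_dir = config$out_dir,
                         seed = config$seed) {
  .stage_log("enrich", seed)
  data_dir <- if (config$input == "synthetic") file.path(out_dir, "data")
              else config$input
  de <- utils::read.table(.need_file(file.path(out_dir, "de", "de.tsv"),
                                     "de"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sets <- read_gmt(.need_file(file.path(data_dir, "genesets.gmt"),
                              "simulate"))
  universe <- unique(de$gene_id)
  out <- do.call(rbind, lapply(sort(unique(de$group)), function(g) {
    sub <- de[de$group == g, , drop = FALSE]
    query <- sub$gene_id[sub$significant & sub$log2fc > 0]
    en <- enrich(query, sets, universe)
    cbind(group = g, en, stringsAsFactors = FALSE)
  }))
  edir <- file.path(out_dir, "enrichment")
  dir.create(edir, recursive = TRUE, showWarnings = FALSE)
  write_results(list(enrichment = out), edir)
  invisible(out)
}

#' Pipeline stage: cohort-level group comparisons from files
#' @inheritParams stage_simulate
#' @param markers marker gene ids tested in the proliferative group.
#' @return the comparison table, invisibly.
#' @export
stage_stats <- function(config, out_dir = config$out_dir,
                        seed = config$seed,
                        markers = c("MKI67L", "TOP2AL", "FOXM1L")) {
  .stage_log("stats", seed)
  data_dir <- if (config$input == "synthetic") file.path(out_dir, "data")
              else config$input
  labels_df <- utils::read.table(
    .need_file(file.path(out_dir, "cluster", "labels.tsv"), "cluster"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  md <- read_metadata(.need_file(file.path(data_dir, "metadata.tsv"),
                                 "simulate"))
  md <- md[match(labels_df$sample_id, md$sample_id), , drop = FALSE]
  labels <- labels_df$group
  counts <- read_counts(.need_file(file.path(data_dir, "counts.tsv"),
                                   "simulate"))
  tp <- tpm(counts$counts, counts$lengths)
  tp <- tp[, labels_df$sample_id, drop = FALSE]
  # group of interest: the one with the highest mean mitotic index
  gm <- tapply(md$mitotic_index, labels, mean)
  g_star <- as.integer(names(gm)[which.max(gm)])
  cmp <- marker_summary(tp, md, labels, markers, g_star)
  gr <- grade_association(md, labels, g_star)
  gr$status <- "ok"
  out <- rbind(cmp, gr)
  out$group_of_interest <- g_star
  sdir <- file.path(out_dir, "stats")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  write_results(list(comparisons = out), sdir)
  invisible(out)
}

#' Pipeline stage: aggregate a JSON + Markdown report
#'
#' Collects whatever stage outputs exist under \code{out_dir}; stages that
#' have not run are reported as missing sections rather than failing.
#'
#' @inheritParams stage_simulate
#' @return the report list, invisibly.
#' @export
stage_report <- function(config, out_dir = config$out_dir,
                         seed = config$seed) {
  .stage_log("report", seed)
  rd <- function(path) if (file.exists(path))
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  sel_path <- file.path(out_dir, "cluster", "selected_k.json")
  selected <- if (file.exists(sel_path))
    jsonlite::read_json(sel_path, simplifyVector = TRUE) else NULL
  labels <- rd(file.path(out_dir, "cluster", "labels.tsv"))
  report <- list(
    seed = seed,
    selected_k = selected,
    group_sizes = if (!is.null(labels))
      as.list(table(labels$group)) else NULL,
    diagnostics = rd(file.path(out_dir, "cluster", "diagnostics.tsv")),
    hmr_summary = rd(file.path(out_dir, "hmr", "hmr_summary.tsv")),
    cnv_summary = rd(file.path(out_dir, "cnv", "cnv_summary.tsv")),
    de_counts = NULL, top_sets = NULL,
    comparisons = rd(file.path(out_dir, "stats", "comparisons.tsv")))
  de <- rd(file.path(out_dir, "de", "de.tsv"))
  if (!is.null(de))
    report$de_counts <- lapply(split(de, de$group),
                               function(s) sum(s$significant))
  en <- rd(file.path(out_dir, "enrichment", "enrichment.tsv"))
  if (!is.null(en)) {
    report$top_sets <- do.call(rbind, lapply(split(en, en$group),
      function(s) utils::head(s[order(s$p), c("group", "set", "overlap",
                                              "p", "q")], 3)))
    rownames(report$top_sets) <- NULL
  }
  truth_path <- file.path(out_dir, "data", "truth.json")
  if (file.exists(truth_path) && !is.null(labels)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    tl <- unlist(truth$labels)[labels$sample_id]
    report$ari_vs_truth <- adjusted_rand_index(labels$group, tl)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  md <- c("# Methylation group pipeline report", "",
          sprintf("Master seed: %s", format(seed)), "")
  section <- function(title, obj, fmt) {
    if (is.null(obj)) c(paste("##", title), "", "missing stage", "")
    else c(paste("##", title), "", fmt(obj), "")
  }
  md <- c(md,
    section("Selected k", report$selected_k, function(s)
      sprintf("k = %s (gap k = %s, delta-area k = %s, concordant = %s)",
              s$k, s$k_gap, s$k_delta, s$concordant)),
    section("Group sizes", report$group_sizes, function(g)
      paste(sprintf("group %s: %s", names(g), unlist(g)), collapse = "; ")),
    section("Stability diagnostics", report$diagnostics, function(d)
      c("```", utils::capture.output(print(d, row.names = FALSE,
                                           digits = 4)), "```")),
    section("HMR summary", report$hmr_summary, function(d)
      sprintf("%d samples; median HMRs per sample %.0f; median island-or-shore fraction %.2f",
              nrow(d), stats::median(d$n_hmrs),
              stats::median(d$frac_island_or_shore))),
    section("CNV summary", report$cnv_summary, function(d)
      sprintf("median genome fraction affected %.3f (range %.3f-%.3f)",
              stats::median(d$genome_fraction_cnv),
              min(d$genome_fraction_cnv), max(d$genome_fraction_cnv))),
    section("Differential expression", report$de_counts, function(d)
      paste(sprintf("group %s: %s significant genes", names(d),
                    unlist(d)), collapse = "; ")),
    section("Top enriched sets", report$top_sets, function(d)
      c("```", utils::capture.output(print(d, row.names = FALSE,
                                           digits = 3)), "```")),
    section("Cohort comparisons", report$comparisons, function(d)
      c("```", utils::capture.output(print(d, row.names = FALSE,
                                           digits = 4)), "```")))
  if (!is.null(report$ari_vs_truth))
    md <- c(md, "## Recovery vs planted truth", "",
            sprintf("adjusted Rand index = %.4f", report$ari_vs_truth), "")
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(report)
}

#' Run the full methylation-group pipeline
#'
#' Executes simulate/ingest, clustering, HMR, CNV, differential expression,
#' enrichment, cohort statistics and the report, in order, under one master
#' seed. Each stage writes its outputs under \code{out_dir} and can also be
#' re-run individually from those files via the \code{stage_*} functions.
#'
#' @param config a [pipeline_config()], a path to a YAML config, or a list.
#' @param out_dir output directory (overrides the config).
#' @param seed master seed (overrides the config).
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- seed
  # validate cheap preconditions before any compute
  if (config$input == "synthetic") {
    scfg <- do.call(synthetic_config, config$synthetic)
    if (max(config$clustering$k_range) > scfg$n_samples)
      stop("k_range maximum exceeds the number of samples")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config),
                   file.path(config$out_dir, "config_used.yaml"))
  if (config$input == "synthetic") stage_simulate(config)
  stage_cluster(config)
  stage_hmr(config)
  stage_cnv(config)
  stage_de(config)
  stage_enrich(config)
  stage_stats(config)
  stage_report(config)
}
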