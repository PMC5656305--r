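# End-to-end orchestration: concordance -> annotation -> DE ->
# classification -> overlaps -> report, from a single validated config.
# Every stage logs its parameters and row counts; the resolved config is
# written beside the outputs so a run can be reproduced from its
# directory alone.

#' Read a two-column read-position TSV (chrom, pos)
#' @param path Path to the TSV (header row required).
#' @return A data.frame `chrom`, `pos` (0-based positions).
#' @export
read_reads <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(tab)))
    stop_data("read table '%s': needs columns chrom, pos", path)
  tab[c("chrom", "pos")]
}

#' Read a chrom-sizes TSV into a genome layout
#' @param path Two-column TSV (`chrom`, `length`), UCSC chrom.sizes style,
#'   with or without header.
#' @return A data.frame `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("^chrom\t", first)
  tab <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("chrom", "length")
  if (any(tab$length <= 0)) stop_data("chromosome lengths must be positive")
  if (anyDuplicated(tab$chrom)) stop_data("duplicated chromosome names")
  tab[c("chrom", "length")]
}

#' Build and validate a pipeline configuration
#'
#' All thresholds are checked against their documented domains before any
#' stage runs; all referenced input paths must exist.
#'
#' @param paths Named list of input paths: `annotation`, `chrom_sizes`,
#'   `peaks_rep1`, `peaks_rep2`, `reads_rep1`, `reads_rep2`, `counts_a`,
#'   `design_a`, `counts_b`, `design_b`, `evidence_b`, and optionally
#'   `courtship`.
#' @param min_mean,max_ratio Concordance thresholds.
#' @param promoter_halfwidth Promoter window half-width (bp).
#' @param alpha,fc DE significance and fold-change thresholds.
#' @param min_total Background-filter threshold (reads).
#' @param n_random Random positions for feature enrichment.
#' @param n_replicates Randomization-test replicates.
#' @param seed Master seed; stage seeds are derived from it.
#' @param exclude_chroms Chromosomes excluded from peak analysis.
#' @param contrast_labels Labels of the two DE contrasts.
#' @param factor_a_mode,factor_b_mode Regulator modes for target
#'   classification (`"activator"` / `"repressor"`).
#' @param universe_mode Universe policy for overlap tests (see
#'   [hypergeom_overlap()]).
#' @return A validated list with class `pipeline_config`.
#' @export
pipeline_config <- function(paths,
                            min_mean = 100, max_ratio = 2,
                            promoter_halfwidth = 1000L,
                            alpha = 0.05, fc = 1.5, min_total = 10,
                            n_random = 50000L, n_replicates = 10000L,
                            seed = 1L,
                            exclude_chroms = character(),
                            contrast_labels = c("factor_a", "factor_b"),
                            factor_a_mode = "activator",
                            factor_b_mode = "repressor",
                            universe_mode = "lenient") {
  thresholds <- concordance_thresholds(min_mean, max_ratio)
  check_count(promoter_halfwidth, "promoter_halfwidth", min = 1L)
  check_proportion(alpha, "alpha", strict = TRUE)
  check_number(fc, "fc", lower = 1, strict_lower = TRUE)
  check_number(min_total, "min_total", lower = 0)
  check_count(n_random, "n_random", min = 1L)
  check_count(n_replicates, "n_replicates", min = 1L)
  required <- c("annotation", "chrom_sizes", "peaks_rep1", "peaks_rep2",
                "reads_rep1", "reads_rep2", "counts_a", "design_a",
                "counts_b", "design_b", "evidence_b")
  miss <- setdiff(required, names(paths))
  if (length(miss))
    stop_data("config missing input path(s): %s", paste(miss, collapse = ", "))
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop_data("input path '%s' does not exist: %s", nm, paths[[nm]])
  }
  structure(list(paths = paths, thresholds = thresholds,
                 promoter_halfwidth = as.integer(promoter_halfwidth),
                 alpha = alpha, fc = fc, min_total = min_total,
                 n_random = as.integer(n_random),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 exclude_chroms = exclude_chroms,
                 contrast_labels = contrast_labels,
                 factor_a_mode = factor_a_mode,
                 factor_b_mode = factor_b_mode,
                 universe_mode = universe_mode),
            class = "pipeline_config")
}

read_design <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(tab)))
    stop_data("design '%s': needs columns sample, condition", path)
  tab
}

#' Run the full convergence pipeline
#'
#' Stages: replicate concordance filtering; promoter annotation and
#' feature enrichment; background filtering and NB differential
#' expression per contrast; direct/indirect target classification; DE
#' overlap, directional breakdown and hub genes; optional courtship
#' statistics. Stage outputs, a line-oriented log and the resolved config
#' are written under `out_dir`.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly also written as
#'   `summary.json`: filtered peak count, promoter gene count, DE counts
#'   per contrast, overlap k/fold/p, direct/indirect counts, hub genes.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       sprintf(...)), log_con)
  }
  run_stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      logmsg("stage %s: FAILED: %s", name, conditionMessage(e))
      stop_data("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    logmsg("stage %s: done", name)
    out
  }
  jsonlite::write_json(
    c(config[setdiff(names(config), "thresholds")],
      list(min_mean = config$thresholds$min_mean,
           max_ratio = config$thresholds$max_ratio)),
    file.path(out_dir, "resolved_config.json"), auto_unbox = TRUE)

  p <- config$paths
  layout <- read_chrom_sizes(p$chrom_sizes)
  annotation <- read_annotation(p$annotation)

  conc <- run_stage("concordance", {
    rep1 <- read_bed(p$peaks_rep1)
    rep2 <- read_bed(p$peaks_rep2)
    reads <- list(rep1 = read_reads(p$reads_rep1),
                  rep2 = read_reads(p$reads_rep2))
    logmsg("concordance: %d + %d peak calls, %d + %d reads, min_mean=%g max_ratio=%g",
           nrow(rep1), nrow(rep2), nrow(reads$rep1), nrow(reads$rep2),
           config$thresholds$min_mean, config$thresholds$max_ratio)
    concordance_pipeline(rep1, rep2, reads,
                         thresholds = config$thresholds,
                         exclude_chroms = config$exclude_chroms)
  })
  kept <- conc$kept
  kept_bed <- kept[c("chrom", "start", "end", "name")]
  kept_bed$score <- kept$mean_norm
  write_bed(kept_bed, file.path(out_dir, "peaks_filtered.bed"))
  write_tsv(conc$regions[c("chrom", "start", "end", "name", "raw_rep1",
                           "raw_rep2", "norm_rep1", "norm_rep2", "mean_norm",
                           "ratio", "qc_flags")],
            file.path(out_dir, "peaks_qc.tsv"))
  logmsg("concordance: %d merged regions, %d kept, %d rejected",
         nrow(conc$regions), nrow(kept), nrow(conc$rejected))

  anno <- run_stage("annotation", {
    assign_nearest_feature(kept, annotation, config$promoter_halfwidth)
  })
  write_tsv(anno, file.path(out_dir, "peak_annotation.tsv"))
  prom_genes <- promoter_genes(anno)
  enrich <- run_stage("feature_enrichment", {
    feature_enrichment(kept, annotation, layout,
                       n_random = config$n_random,
                       promoter_halfwidth = config$promoter_halfwidth,
                       seed = derive_seed(config$seed, 3L))
  })
  write_tsv(enrich, file.path(out_dir, "feature_enrichment.tsv"))
  coverage <- genome_coverage_fraction(kept, layout)
  logmsg("annotation: %d promoter genes, genome coverage %.4f",
         length(prom_genes), coverage)

  de <- list()
  background <- list()
  for (i in 1:2) {
    label <- config$contrast_labels[i]
    stage <- run_stage(paste0("de_", label), {
      counts <- read_count_matrix(p[[c("counts_a", "counts_b")[i]]])
      design <- read_design(p[[c("design_a", "design_b")[i]]])
      counts <- counts[, design$sample, drop = FALSE]
      bg <- background_filter(counts, config$min_total)
      logmsg("de_%s: %d genes, %d excluded (< %g reads), %d in background",
             label, nrow(counts), length(bg$excluded), config$min_total,
             length(bg$background))
      list(bg = bg,
           de = nb_de_test(counts[bg$background, , drop = FALSE],
                           design$condition, alpha = config$alpha,
                           fc_threshold = config$fc))
    })
    de[[label]] <- stage$de
    background[[label]] <- stage$bg
    write_tsv(de[[label]], file.path(out_dir, paste0("de_", label, ".tsv")))
  }

  evidence_b <- read_gene_list(p$evidence_b, label = "evidence_b")
  class_a <- run_stage("classify", {
    classify_targets(config$factor_a_mode, prom_genes, de[[1L]])
  })
  class_b <- classify_targets(config$factor_b_mode, evidence_b, de[[2L]])
  write_tsv(rbind(cbind(factor = config$contrast_labels[1L], class_a),
                  cbind(factor = config$contrast_labels[2L], class_b)),
            file.path(out_dir, "target_classification.tsv"))

  overlaps <- run_stage("overlaps", {
    sig_a <- de[[1L]]$gene_id[de[[1L]]$status != "ns"]
    sig_b <- de[[2L]]$gene_id[de[[2L]]$status != "ns"]
    universe_de <- union(background[[1L]]$background,
                         background[[2L]]$background)
    de_overlap <- hypergeom_overlap(sig_a, sig_b, universe_de,
                                    mode = config$universe_mode)
    genomic_overlap <- hypergeom_overlap(prom_genes, evidence_b$members,
                                         annotation$gene_id,
                                         mode = config$universe_mode)
    breakdown <- directional_breakdown(de[[1L]], de[[2L]])
    hubs <- hub_genes(genomic_overlap$shared, de_overlap$shared)
    list(de_overlap = de_overlap, genomic_overlap = genomic_overlap,
         breakdown = breakdown, hubs = hubs)
  })
  write_tsv(data.frame(
    comparison = c("de_overlap", "genomic_overlap"),
    K = c(overlaps$de_overlap$K, overlaps$genomic_overlap$K),
    n = c(overlaps$de_overlap$n, overlaps$genomic_overlap$n),
    k = c(overlaps$de_overlap$k, overlaps$genomic_overlap$k),
    N = c(overlaps$de_overlap$N, overlaps$genomic_overlap$N),
    expected = c(overlaps$de_overlap$expected, overlaps$genomic_overlap$expected),
    fold = c(overlaps$de_overlap$fold, overlaps$genomic_overlap$fold),
    p = c(overlaps$de_overlap$p, overlaps$genomic_overlap$p)
  ), file.path(out_dir, "overlap_report.tsv"))

  behavior <- NULL
  if (!is.null(p$courtship)) {
    behavior <- run_stage("behavior", {
      obs <- read_courtship(p$courtship)
      learning_results(obs, n_replicates = config$n_replicates,
                       seed = derive_seed(config$seed, 7L))
    })
  }

  de_counts <- lapply(de, function(d) {
    c(up = sum(d$status == "up"), down = sum(d$status == "down"),
      total = sum(d$status != "ns"))
  })
  summary <- list(
    n_merged_regions = nrow(conc$regions),
    n_filtered_peaks = nrow(kept),
    genome_coverage_fraction = coverage,
    n_promoter_genes = length(prom_genes),
    de = de_counts,
    de_overlap = overlaps$de_overlap[c("K", "n", "k", "N", "expected",
                                       "fold", "p")],
    genomic_overlap = overlaps$genomic_overlap[c("K", "n", "k", "N",
                                                 "expected", "fold", "p")],
    directional = list(table = as.vector(overlaps$breakdown$table),
                       n_shared = overlaps$breakdown$n_shared,
                       fisher_p = overlaps$breakdown$fisher_p),
    classification = list(
      direct_a = sum(class_a$class == "potential_direct"),
      indirect_a = sum(class_a$class == "potential_indirect"),
      direct_b = sum(class_b$class == "potential_direct"),
      indirect_b = sum(class_b$class == "potential_indirect")),
    hub_genes = overlaps$hubs,
    behavior = if (!is.null(behavior)) list(
      per_genotype = behavior$per_genotype,
      delta_li = behavior$between$delta_li,
      randomization_p = behavior$between$p)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logmsg("pipeline complete")
  invisible(summary)
}

#' Write a complete synthetic study to disk
#'
#' Generates a genome, two-replicate peak calls, two count-matrix
#' contrasts, a mark-loss evidence gene list for the second factor and a
#' courtship table, writes everything (plus ground-truth tables) as plain
#' text under `dir`, and returns a ready [pipeline_config()].
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config` whose paths point into `dir`; truth tables
#'   are in `dir/truth_*.tsv`.
#' @export
simulate_study <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(seed = derive_seed(seed, 101L))
  peaks <- simulate_peak_replicates(genome, seed = derive_seed(seed, 102L))
  cnts <- simulate_counts(n_genes = nrow(genome$annotation),
                          seed = derive_seed(seed, 103L))
  court <- simulate_courtship(seed = derive_seed(seed, 104L))

  set.seed(derive_seed(seed, 105L))
  # mark-loss evidence for factor B: a random third of all genes
  evidence_b <- sort(sample(genome$annotation$gene_id,
                            round(nrow(genome$annotation) / 3)))

  fp <- function(name) file.path(dir, name)
  write_annotation(genome$annotation, fp("annotation.tsv"))
  write_tsv(genome$layout, fp("chrom_sizes.tsv"))
  write_bed(peaks$peaks_rep1, fp("peaks_rep1.bed"))
  write_bed(peaks$peaks_rep2, fp("peaks_rep2.bed"))
  write_tsv(peaks$reads$rep1, fp("reads_rep1.tsv"))
  write_tsv(peaks$reads$rep2, fp("reads_rep2.tsv"))
  labels <- names(cnts$counts)
  for (i in 1:2) {
    write_count_matrix(cnts$counts[[i]], fp(sprintf("counts_%s.tsv", c("a", "b")[i])))
    write_tsv(data.frame(sample = colnames(cnts$counts[[i]]),
                         condition = as.character(cnts$condition[[i]])),
              fp(sprintf("design_%s.tsv", c("a", "b")[i])))
  }
  writeLines(evidence_b, fp("evidence_b.txt"))
  write_tsv(court$observations, fp("courtship.tsv"))
  write_tsv(peaks$truth, fp("truth_peaks.tsv"))
  write_tsv(cnts$truth, fp("truth_de.tsv"))
  write_tsv(court$truth, fp("truth_courtship.tsv"))

  pipeline_config(
    paths = list(annotation = fp("annotation.tsv"),
                 chrom_sizes = fp("chrom_sizes.tsv"),
                 peaks_rep1 = fp("peaks_rep1.bed"),
                 peaks_rep2 = fp("peaks_rep2.bed"),
                 reads_rep1 = fp("reads_rep1.tsv"),
                 reads_rep2 = fp("reads_rep2.tsv"),
                 counts_a = fp("counts_a.tsv"),
                 design_a = fp("design_a.tsv"),
                 counts_b = fp("counts_b.tsv"),
                 design_b = fp("design_b.tsv"),
                 evidence_b = fp("evidence_b.txt"),
                 courtship = fp("courtship.tsv")),
    contrast_labels = labels, seed = seed, ...)
}
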