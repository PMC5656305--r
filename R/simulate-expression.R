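# Synthetic RNA-seq count matrices for two mutant-vs-control contrasts
# with a controlled fraction of shared differentially expressed genes.

#' Simulate count matrices for two contrasts with planted DE truth
#'
#' Gene-wise baseline means are log-normal; differential genes shift the
#' mutant group mean by a factor of `2^lfc` (direction random per gene and,
#' for shared genes, independent between the two contrasts unless
#' `shared_same_direction = TRUE`). Counts are negative binomial with
#' variance `mu + dispersion * mu^2`. A `lowly_expressed_fraction` of genes
#' is given baseline means so small that their total expected counts per
#' contrast fall below 10, exercising the background filter.
#'
#' DE gene assignment is deterministic in counts: exactly
#' `round(de_fraction * n_genes)` genes are DE in each contrast and
#' `round(shared_de_fraction * n_genes)` of them are shared.
#'
#' @param n_genes Number of genes.
#' @param n_reps_per_group Replicates per condition (>= 2).
#' @param contrasts Character vector of two contrast labels.
#' @param de_fraction Fraction of genes DE in each contrast.
#' @param shared_de_fraction Fraction of genes DE in both contrasts
#'   (must not exceed `de_fraction`).
#' @param lfc Absolute log2 fold change of DE genes (non-zero when
#'   `de_fraction > 0`).
#' @param dispersion NB dispersion.
#' @param lowly_expressed_fraction Fraction of genes planted below the
#'   10-read background threshold.
#' @param baseline_log_mean,baseline_log_sd Log-scale parameters of the
#'   baseline mean distribution.
#' @param shared_same_direction Force shared DE genes to move in the same
#'   direction in both contrasts.
#' @param seed Integer seed.
#' @return A list with class `count_sim`: `counts` (named list of integer
#'   matrices, one per contrast; columns `<label>_ctl_i` / `<label>_mut_i`),
#'   `condition` (named list of factor vectors), and `truth` (data.frame
#'   `gene_id`, `contrast`, `status` in up/down/null, `true_lfc`).
#' @export
simulate_counts <- function(n_genes = 1000L,
                            n_reps_per_group = 3L,
                            contrasts = c("factor_a", "factor_b"),
                            de_fraction = 0.1,
                            shared_de_fraction = 0.05,
                            lfc = 2,
                            dispersion = 0.05,
                            lowly_expressed_fraction = 0.1,
                            baseline_log_mean = log(100),
                            baseline_log_sd = 1,
                            shared_same_direction = FALSE,
                            seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_reps_per_group <- check_count(n_reps_per_group, "n_reps_per_group", min = 2L)
  check_proportion(de_fraction, "de_fraction")
  check_proportion(shared_de_fraction, "shared_de_fraction")
  check_proportion(lowly_expressed_fraction, "lowly_expressed_fraction")
  check_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  if (length(contrasts) != 2L || anyDuplicated(contrasts))
    stop_data("'contrasts' must be two distinct labels")
  if (shared_de_fraction > de_fraction)
    stop_data("shared_de_fraction (%g) cannot exceed de_fraction (%g)",
              shared_de_fraction, de_fraction)
  if (de_fraction > 0 && lfc == 0)
    stop_data("a DE gene with zero log2 fold change is contradictory; set lfc != 0 or de_fraction = 0")

  n_de <- round(de_fraction * n_genes)
  n_shared <- round(shared_de_fraction * n_genes)
  n_de_any <- 2L * n_de - n_shared
  if (n_de_any > n_genes)
    stop_data("de_fraction/shared_de_fraction imply %d distinct DE genes but only %d genes",
              n_de_any, n_genes)
  n_low <- min(round(lowly_expressed_fraction * n_genes), n_genes - n_de_any)

  set.seed(derive_seed(seed, 37L))
  gene_id <- sprintf("g%05d", seq_len(n_genes))

  shared_idx <- seq_len(n_shared)
  only_a <- seq_len(n_de - n_shared) + n_shared
  only_b <- seq_len(n_de - n_shared) + n_shared + length(only_a)
  de_idx <- list(c(shared_idx, only_a), c(shared_idx, only_b))
  low_idx <- n_genes - seq_len(n_low) + 1L # from the tail: disjoint from DE genes

  base_mu <- exp(stats::rnorm(n_genes, baseline_log_mean, baseline_log_sd))
  n_samples <- 2L * n_reps_per_group
  if (n_low > 0L)
    base_mu[low_idx] <- stats::runif(n_low, 0.01, 8 / n_samples)

  size <- 1 / dispersion
  shared_sign <- sample(c(-1, 1), n_shared, replace = TRUE)
  out_counts <- list()
  out_cond <- list()
  truth_list <- list()
  for (ct in 1:2) {
    sign <- numeric(n_genes)
    idx <- de_idx[[ct]]
    sign[idx] <- sample(c(-1, 1), length(idx), replace = TRUE)
    if (shared_same_direction && n_shared > 0L)
      sign[shared_idx] <- shared_sign
    true_lfc <- sign * lfc
    mu_ctl <- base_mu
    mu_mut <- base_mu * 2^true_lfc
    counts <- matrix(0L, n_genes, n_samples)
    for (j in seq_len(n_reps_per_group)) {
      counts[, j] <- stats::rnbinom(n_genes, mu = mu_ctl, size = size)
      counts[, n_reps_per_group + j] <- stats::rnbinom(n_genes, mu = mu_mut, size = size)
    }
    label <- contrasts[ct]
    colnames(counts) <- c(sprintf("%s_ctl_%d", label, seq_len(n_reps_per_group)),
                          sprintf("%s_mut_%d", label, seq_len(n_reps_per_group)))
    rownames(counts) <- gene_id
    out_counts[[label]] <- counts
    out_cond[[label]] <- factor(rep(c("control", "mutant"),
                                    each = n_reps_per_group),
                                levels = c("control", "mutant"))
    truth_list[[label]] <- data.frame(
      gene_id = gene_id,
      contrast = label,
      status = ifelse(sign > 0, "up", ifelse(sign < 0, "down", "null")),
      true_lfc = true_lfc,
      stringsAsFactors = FALSE
    )
  }
  structure(list(counts = out_counts, condition = out_cond,
                 truth = do.call(rbind, truth_list)),
            class = "count_sim")
}
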