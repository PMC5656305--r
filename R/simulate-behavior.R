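# Synthetic courtship-conditioning observations.
#
# Courtship indices are bounded proportions, so they are drawn from beta
# distributions parameterized by (mean, concentration): shape1 = m * c,
# shape2 = (1 - m) * c. Trained-group suppression is genotype-specific,
# which is what the learning index measures.

#' Simulate courtship observations with known learning indices
#'
#' Group sizes default to the scale of a typical courtship-conditioning
#' experiment (56-62 flies per genotype and condition).
#'
#' @param n_per_group Named integer vector of group sizes with names
#'   `<genotype>.naive` / `<genotype>.trained` for each genotype in
#'   `trained_mean_by_genotype`, or an unnamed vector of length
#'   `2 * n_genotypes` ordered (naive, trained) per genotype.
#' @param naive_mean Mean naive courtship index, shared across genotypes.
#' @param trained_mean_by_genotype Named numeric vector: mean trained
#'   courtship index per genotype.
#' @param concentration Beta concentration (larger = tighter spread).
#' @param seed Integer seed.
#' @return A list with class `courtship_sim`: `observations` (data.frame
#'   `fly_id`, `genotype`, `condition`, `ci`) and `truth` (data.frame
#'   `genotype`, `naive_mean`, `trained_mean`, `true_li` where
#'   `true_li = (naive_mean - trained_mean) / naive_mean`).
#' @export
simulate_courtship <- function(n_per_group = c(control.naive = 56L,
                                               control.trained = 59L,
                                               rnai.naive = 60L,
                                               rnai.trained = 62L),
                               naive_mean = 0.72,
                               trained_mean_by_genotype = c(control = 0.30,
                                                            rnai = 0.65),
                               concentration = 10,
                               seed = 1L) {
  check_proportion(naive_mean, "naive_mean", strict = TRUE)
  for (m in trained_mean_by_genotype)
    check_proportion(m, "trained_mean_by_genotype", strict = TRUE)
  check_number(concentration, "concentration", lower = 0, strict_lower = TRUE)
  genotypes <- names(trained_mean_by_genotype)
  if (is.null(genotypes) || any(!nzchar(genotypes)))
    stop_data("trained_mean_by_genotype must be named by genotype")
  want <- as.vector(rbind(paste0(genotypes, ".naive"),
                          paste0(genotypes, ".trained")))
  if (is.null(names(n_per_group))) {
    if (length(n_per_group) != length(want))
      stop_data("n_per_group must have %d entries (naive, trained per genotype)",
                length(want))
    names(n_per_group) <- want
  }
  if (!all(want %in% names(n_per_group)))
    stop_data("n_per_group missing group(s): %s",
              paste(setdiff(want, names(n_per_group)), collapse = ", "))
  for (g in want) check_count(n_per_group[[g]], g, min = 1L)

  set.seed(derive_seed(seed, 53L))
  rows <- list()
  fly <- 0L
  for (g in genotypes) {
    for (cond in c("naive", "trained")) {
      n <- as.integer(n_per_group[[paste0(g, ".", cond)]])
      m <- if (cond == "naive") naive_mean else trained_mean_by_genotype[[g]]
      ci <- stats::rbeta(n, m * concentration, (1 - m) * concentration)
      rows[[paste0(g, ".", cond)]] <- data.frame(
        fly_id = sprintf("fly_%04d", fly + seq_len(n)),
        genotype = g, condition = cond, ci = ci,
        stringsAsFactors = FALSE
      )
      fly <- fly + n
    }
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  truth <- data.frame(
    genotype = genotypes,
    naive_mean = naive_mean,
    trained_mean = unname(trained_mean_by_genotype),
    true_li = (naive_mean - unname(trained_mean_by_genotype)) / naive_mean,
    stringsAsFactors = FALSE
  )
  structure(list(observations = validate_courtship(obs), truth = truth),
            class = "courtship_sim")
}
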