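# Courtship-conditioning statistics: learning index, Mann-Whitney
# comparison of naive vs trained courtship indices within a genotype, and
# a bootstrap randomization test on the learning-index difference between
# genotypes.

#' Learning index from naive and trained courtship indices
#'
#' LI = (mean naive CI - mean trained CI) / mean naive CI. Negative
#' values (trained flies courting more) are permitted; LI <= 1 always.
#'
#' @param naive,trained Numeric vectors of courtship indices in [0, 1].
#' @return The learning index.
#' @export
learning_index <- function(naive, trained) {
  if (length(naive) == 0L || length(trained) == 0L)
    stop_data("both groups must be non-empty")
  mn <- mean(naive)
  if (mn <= 0)
    stop_data("mean naive courtship index is 0: learning index undefined")
  (mn - mean(trained)) / mn
}

#' Mann-Whitney comparison of two courtship-index groups
#'
#' Uses the exact distribution when the combined sample size is <= 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List: `U` (statistic for `group_a`), `p` (two-sided),
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_ci <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop_data("both groups must be non-empty")
  combined <- c(group_a, group_b)
  ties <- anyDuplicated(combined) > 0L
  exact <- length(combined) <= 12L && !ties
  # U from mid-ranks (equals wilcox.test's W for group_a)
  r <- rank(combined)
  U <- sum(r[seq_along(group_a)]) - length(group_a) * (length(group_a) + 1) / 2
  if (length(unique(combined)) == 1L)
    return(list(U = U, p = 1, method = "degenerate_all_tied"))
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(U = U, p = min(p, 1), method = if (exact) "exact" else "normal_approx")
}

#' Bootstrap randomization test on the learning-index difference
#'
#' The observed statistic is `LI(genotype_a) - LI(genotype_b)`. The null
#' distribution pools the courtship indices of both genotypes within each
#' condition, resamples groups of the original per-genotype-per-condition
#' sizes with replacement, and recomputes the difference `n_replicates`
#' times. The two-sided p uses the add-one estimator
#' `(1 + #{|delta*| >= |delta_obs|}) / (1 + n_replicates)`, so p is never
#' exactly zero. A label-permutation variant (resampling without
#' replacement) is available via `scheme = "permutation"`.
#'
#' @param observations Courtship data.frame (`genotype`, `condition`,
#'   `ci`; see [read_courtship()]).
#' @param genotype_a,genotype_b The two genotypes to compare (default:
#'   first two in the table).
#' @param n_replicates Number of resampling replicates (>= 1).
#' @param seed Integer seed.
#' @param scheme `"bootstrap"` (with replacement, default) or
#'   `"permutation"`.
#' @return List with class `li_test`: `li_a`, `li_b`, `delta_li`, `p`,
#'   `n_replicates`, `scheme`, and the per-group sizes.
#' @export
randomization_test_li <- function(observations, genotype_a = NULL,
                                  genotype_b = NULL, n_replicates = 10000L,
                                  seed = 1L,
                                  scheme = c("bootstrap", "permutation")) {
  scheme <- match.arg(scheme)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  genos <- unique(observations$genotype)
  genotype_a <- genotype_a %||% genos[1L]
  genotype_b <- genotype_b %||% genos[2L]
  pull <- function(g, cond) {
    x <- observations$ci[observations$genotype == g &
                           observations$condition == cond]
    if (length(x) == 0L)
      stop_data("genotype '%s' has no %s flies", g, cond)
    x
  }
  na_ <- pull(genotype_a, "naive"); ta_ <- pull(genotype_a, "trained")
  nb_ <- pull(genotype_b, "naive"); tb_ <- pull(genotype_b, "trained")
  li_a <- learning_index(na_, ta_)
  li_b <- learning_index(nb_, tb_)
  delta_obs <- li_a - li_b

  pool_naive <- c(na_, nb_)
  pool_trained <- c(ta_, tb_)
  set.seed(derive_seed(seed, 97L))
  boot_means <- function(pool, n, B) {
    .colMeans(pool[sample.int(length(pool), n * B, replace = TRUE)], n, B)
  }
  if (scheme == "bootstrap") {
    mna <- boot_means(pool_naive, length(na_), n_replicates)
    mnb <- boot_means(pool_naive, length(nb_), n_replicates)
    mta <- boot_means(pool_trained, length(ta_), n_replicates)
    mtb <- boot_means(pool_trained, length(tb_), n_replicates)
  } else {
    perm_means <- function(pool, n1) {
      m <- vapply(seq_len(n_replicates), function(i) {
        idx <- sample.int(length(pool), n1)
        c(mean(pool[idx]), mean(pool[-idx]))
      }, numeric(2L))
      list(a = m[1L, ], b = m[2L, ])
    }
    pn <- perm_means(pool_naive, length(na_))
    pt <- perm_means(pool_trained, length(ta_))
    mna <- pn$a; mnb <- pn$b; mta <- pt$a; mtb <- pt$b
  }
  delta_star <- (1 - mta / mna) - (1 - mtb / mnb)
  p <- (1 + sum(abs(delta_star) >= abs(delta_obs))) / (1 + n_replicates)
  structure(list(
    genotype_a = genotype_a, genotype_b = genotype_b,
    li_a = li_a, li_b = li_b, delta_li = delta_obs, p = p,
    n_replicates = n_replicates, scheme = scheme,
    n = c(naive_a = length(na_), trained_a = length(ta_),
          naive_b = length(nb_), trained_b = length(tb_))
  ), class = "li_test")
}

#' Full learning-result summary for a courtship table
#'
#' Per genotype: group means, learning index and the within-genotype
#' Mann-Whitney p; between the two genotypes: the learning-index
#' difference and its randomization-test p.
#'
#' @inheritParams randomization_test_li
#' @return List: `per_genotype` (data.frame), `between` (an `li_test`).
#' @export
learning_results <- function(observations, genotype_a = NULL,
                             genotype_b = NULL, n_replicates = 10000L,
                             seed = 1L) {
  genos <- unique(observations$genotype)
  genotype_a <- genotype_a %||% genos[1L]
  genotype_b <- genotype_b %||% genos[2L]
  per <- do.call(rbind, lapply(c(genotype_a, genotype_b), function(g) {
    nv <- observations$ci[observations$genotype == g &
                            observations$condition == "naive"]
    tr <- observations$ci[observations$genotype == g &
                            observations$condition == "trained"]
    mw <- mann_whitney_ci(nv, tr)
    data.frame(genotype = g, n_naive = length(nv), n_trained = length(tr),
               mean_ci_naive = mean(nv), mean_ci_trained = mean(tr),
               li = learning_index(nv, tr), mann_whitney_p = mw$p,
               stringsAsFactors = FALSE)
  }))
  between <- randomization_test_li(observations, genotype_a, genotype_b,
                                   n_replicates = n_replicates, seed = seed)
  list(per_genotype = per, between = between)
}
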