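test_that("make_genome places genes validly and deterministically", {
  g <- make_genome(1L, 1e6, 0L, seed = 1)
  expect_equal(nrow(g$annotation), 0L)
  expect_equal(nrow(g$layout), 1L)

  g1 <- make_genome(1L, 1e6, 100L, seed = 7)
  g2 <- make_genome(1L, 1e6, 100L, seed = 7)
  expect_identical(g1, g2)

  ann <- g1$annotation
  expect_equal(nrow(ann), 100L)
  expect_true(all(ann$strand %in% c("+", "-")))
  expect_true(all(pmax(ann$tss, ann$tes) < 1e6))
  expect_true(all(pmin(ann$tss, ann$tes) >= 0))
  minus <- ann$strand == "-"
  expect_true(all(ann$tss[minus] > ann$tes[minus]))
  expect_true(all(ann$tss[!minus] < ann$tes[!minus]))
  # gene bodies do not overlap
  gr <- GenomicRanges::GRanges(ann$chrom,
    IRanges::IRanges(pmin(ann$tss, ann$tes) + 1L, pmax(ann$tss, ann$tes)))
  expect_true(all(GenomicRanges::countOverlaps(gr, gr) == 1L))

  expect_error(make_genome(1L, 1e4, 100L, seed = 1), "capacity")
})

test_that("peak simulator plants classes as labelled and reads match counts", {
  g <- make_genome(seed = 2)
  sim <- simulate_peak_replicates(g, n_true_promoter = 50L, n_true_distal = 0L,
                                  n_low_signal = 0L, n_discordant = 0L,
                                  mean_depth = 500, seed = 3)
  expect_equal(nrow(sim$regions), 50L)
  expect_true(all(sim$counts > 0))
  # every promoter-class region is centered within 1 kb of a TSS
  mid <- floor((sim$regions$start + sim$regions$end) / 2)
  dmin <- vapply(seq_len(50L), function(i) {
    on_chrom <- g$annotation$chrom == sim$regions$chrom[i]
    min(abs(g$annotation$tss[on_chrom] - mid[i]))
  }, 1)
  expect_true(all(dmin <= 1000))
  # read positions are consistent with the per-region counts
  cnt <- count_reads_in_regions(sim$regions, sim$reads)
  expect_equal(unname(cnt[, 1]), unname(sim$counts[, 1]))
  expect_equal(unname(cnt[, 2]), unname(sim$counts[, 2]))

  empty <- simulate_peak_replicates(g, 0L, 0L, 0L, 0L, seed = 1)
  expect_equal(nrow(empty$regions), 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("discordant regions carry the planted replicate imbalance", {
  g <- make_genome(seed = 2)
  sim <- simulate_peak_replicates(g, n_true_promoter = 0L, n_true_distal = 0L,
                                  n_low_signal = 0L, n_discordant = 400L,
                                  mean_depth = 500, dispersion = 0.05,
                                  seed = 5)
  norm <- normalize_to_library_size(sim$counts, sim$library_sizes)
  ratio <- pmax(norm[, 1], norm[, 2]) / pmin(norm[, 1], norm[, 2])
  # at mean 500 and dispersion 0.05 a 3-fold planted imbalance puts the
  # per-region P(ratio >= 2) near 0.89 (Monte-Carlo); the bulk of the
  # class must show the imbalance and its median must sit near 3
  expect_gte(mean(ratio >= 2), 0.8)
  expect_lt(abs(stats::median(ratio) - 3) / 3, 0.15)
})

test_that("count simulator honours the DE/shared bookkeeping exactly", {
  sim <- simulate_counts(n_genes = 1000L, de_fraction = 0.1,
                         shared_de_fraction = 0.05, seed = 4)
  tr <- split(sim$truth, sim$truth$contrast)
  de_sets <- lapply(tr, function(t) t$gene_id[t$status != "null"])
  expect_equal(lengths(de_sets), c(100L, 100L), ignore_attr = TRUE)
  expect_length(intersect(de_sets[[1]], de_sets[[2]]), 50L)
  expect_true(all(sim$truth$true_lfc[sim$truth$status == "null"] == 0))

  null_sim <- simulate_counts(n_genes = 50L, de_fraction = 0,
                              shared_de_fraction = 0, seed = 1)
  expect_true(all(null_sim$truth$status == "null"))

  expect_error(simulate_counts(de_fraction = 0.1, lfc = 0), "contradictory")
  expect_error(simulate_counts(de_fraction = 0.05, shared_de_fraction = 0.1),
               "cannot exceed")

  # lowly expressed genes fall under the 10-read background threshold
  low <- simulate_counts(n_genes = 1000L, de_fraction = 0,
                         shared_de_fraction = 0,
                         lowly_expressed_fraction = 0.2, seed = 6)
  bg <- background_filter(low$counts[[1]])
  expect_gte(length(bg$excluded), 150L)
})

test_that("null-gene counts match the NB variance-mean relationship", {
  d <- 0.1
  sim <- simulate_counts(n_genes = 6000L, de_fraction = 0,
                         shared_de_fraction = 0, dispersion = d,
                         lowly_expressed_fraction = 0, n_reps_per_group = 5L,
                         seed = 8)
  cm <- sim$counts[[1]]
  m <- rowMeans(cm)
  v <- apply(cm, 1, stats::var)
  sel <- m > 50 & m < 500
  d_hat <- sum(v[sel] - m[sel]) / sum(m[sel]^2)
  expect_lt(abs(d_hat - d) / d, 0.2)
})

test_that("courtship simulator records the true learning indices", {
  sim <- simulate_courtship(
    n_per_group = c(a.naive = 56L, a.trained = 59L, b.naive = 60L, b.trained = 62L),
    naive_mean = 0.8, trained_mean_by_genotype = c(a = 0.2, b = 0.8),
    concentration = 10, seed = 9)
  expect_equal(sim$truth$true_li, c(0.75, 0))
  tab <- table(sim$observations$genotype, sim$observations$condition)
  expect_equal(as.vector(tab), c(56L, 60L, 59L, 62L))
  expect_true(all(sim$observations$ci >= 0 & sim$observations$ci <= 1))
  rerun <- simulate_courtship(
    n_per_group = c(a.naive = 56L, a.trained = 59L, b.naive = 60L, b.trained = 62L),
    naive_mean = 0.8, trained_mean_by_genotype = c(a = 0.2, b = 0.8),
    concentration = 10, seed = 9)
  expect_identical(sim, rerun)
})

test_that("simulator truth tables agree with the generated objects", {
  g <- make_genome(n_chromosomes = 2L, chrom_length = 4e6, n_genes = 400L,
                   seed = 10)
  sim <- simulate_peak_replicates(g, 100L, 50L, 30L, 30L, seed = 10)
  expect_setequal(sim$truth$region_id, sim$regions$name)
  expect_setequal(sim$truth$region_id, rownames(sim$counts))
  expect_setequal(sim$peaks_rep1$name, sim$truth$region_id)

  cs <- simulate_counts(n_genes = 200L, seed = 10)
  expect_setequal(unique(cs$truth$gene_id), rownames(cs$counts[[1]]))
})
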