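test_that("merge_regions unions, sorts and merges book-ended intervals", {
  expect_equal(
    merge_regions(peak_df("chr1", 10L, 20L), peak_df("chr1", 15L, 30L))[1:3],
    peak_df("chr1", 10L, 30L))
  expect_equal(
    merge_regions(peak_df("chr1", 10L, 20L), peak_df("chr1", 20L, 30L))[1:3],
    peak_df("chr1", 10L, 30L))
  expect_equal(
    merge_regions(peak_df("chr1", 10L, 20L), peak_df(character(), integer(), integer()))[1:3],
    peak_df("chr1", 10L, 20L))
  # disjoint, sorted output; union preserved across chromosomes
  out <- merge_regions(peak_df(c("chr2", "chr1"), c(5L, 100L), c(9L, 150L)),
                       peak_df("chr1", 10L, 20L))
  expect_equal(out$chrom, c("chr1", "chr1", "chr2"))
  expect_true(all(diff(out$start[out$chrom == "chr1"]) > 0))
  expect_error(merge_regions(peak_df("chr1", 30L, 20L), peak_df("chr1", 1L, 2L)),
               "start >= end")
})

test_that("read counting respects half-open boundaries and disjointness", {
  region <- peak_df("chr1", 10L, 20L)
  region$name <- "r1"
  reads <- data.frame(chrom = "chr1", pos = c(5L, 15L, 25L))
  expect_equal(unname(count_reads_in_regions(region, reads)[1, 1]), 1L)
  reads2 <- data.frame(chrom = "chr1", pos = c(10L, 19L, 20L))
  expect_equal(unname(count_reads_in_regions(region, reads2)[1, 1]), 2L)
  none <- data.frame(chrom = character(), pos = integer())
  expect_equal(unname(count_reads_in_regions(region, none)[1, 1]), 0L)
  overlapping <- peak_df("chr1", c(10L, 15L), c(20L, 25L))
  expect_error(count_reads_in_regions(overlapping, reads), "disjoint")
})

test_that("library-size normalization rescales to the mean library", {
  expect_equal(unname(normalize_to_library_size(cbind(100, 100), c(1e6, 1e6))),
               cbind(100, 100), ignore_attr = TRUE)
  out <- normalize_to_library_size(cbind(100, 200), c(1e6, 2e6))
  expect_equal(unname(out), cbind(150, 150), ignore_attr = TRUE)
  out0 <- normalize_to_library_size(cbind(0, 50), c(3e6, 1e6))
  expect_equal(out0[1, 1], 0)
  expect_error(normalize_to_library_size(cbind(1, 1), c(0, 1e6)), "positive")
})

test_that("concordance filter applies strict thresholds and flags rejects", {
  pk <- data.frame(name = paste0("r", 1:5),
                   norm_rep1 = c(150, 300, 120, 0, 0),
                   norm_rep2 = c(90, 100, 80, 500, 0))
  res <- concordance_filter(pk)
  expect_equal(res$kept$name, "r1") # mean 120, ratio 1.67
  rej <- res$rejected
  expect_equal(nrow(rej) + nrow(res$kept), 5L)
  expect_match(rej$qc_flags[rej$name == "r2"], "high_ratio")
  expect_match(rej$qc_flags[rej$name == "r3"], "low_mean") # mean exactly 100
  expect_match(rej$qc_flags[rej$name == "r4"], "high_ratio") # one zero: Inf
  expect_match(rej$qc_flags[rej$name == "r5"], "low_mean") # both zero
  expect_true(all(nzchar(rej$qc_flags)))
  expect_error(concordance_thresholds(max_ratio = 0.5), "domain")
})

test_that("cluster QC flags the planted flat-noise cluster", {
  set.seed(1)
  n <- 50L
  mid <- seq(5000L, by = 10000L, length.out = 2L * n)
  peaks <- peak_df("chr1", mid - 200L, mid + 200L)
  # strong center signal for the first 50, sparse uniform noise for the rest
  strong <- data.frame(
    chrom = "chr1",
    pos = rep(mid[1:n], each = 200L) + round(stats::rnorm(200L * n, 0, 60)))
  flat <- data.frame(
    chrom = "chr1",
    pos = round(stats::runif(10L * n, rep(mid[(n + 1):(2L * n)] - 1000, each = 10L),
                             rep(mid[(n + 1):(2L * n)] + 1000, each = 10L))))
  cq <- cluster_qc(peaks, rbind(strong, flat), k = 2L, seed = 3)
  truth_noise <- c(rep(FALSE, n), rep(TRUE, n))
  expect_gte(mean(cq$bad_cluster == truth_noise), 0.95)

  expect_error(cluster_qc(peaks[1:3, ], strong, k = 10L), "exceeds")
})

test_that("identical profiles produce no flagged cluster", {
  mid <- seq(5000L, by = 10000L, length.out = 20L)
  peaks <- peak_df("chr1", mid - 200L, mid + 200L)
  reads <- data.frame(chrom = "chr1",
                      pos = rep(mid, each = 10L) + rep(c(-30L, -20L, -10L, -5L, 0L,
                                                         5L, 10L, 20L, 30L, 40L), 20L))
  cq <- cluster_qc(peaks, reads, k = 2L, seed = 2)
  expect_length(cq$flagged_clusters, 0L)
})

test_that("cascade output is conserved and order-invariant", {
  g <- make_genome(n_chromosomes = 2L, chrom_length = 4e6, n_genes = 300L,
                   seed = 20)
  sim <- simulate_peak_replicates(g, 60L, 30L, 20L, 20L, seed = 21)
  res <- concordance_pipeline(sim$peaks_rep1, sim$peaks_rep2, sim$reads,
                              library_sizes = sim$library_sizes)
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(res$regions))
  shuf <- sample(nrow(sim$peaks_rep1))
  res2 <- concordance_pipeline(sim$peaks_rep1[shuf, ], sim$peaks_rep2, sim$reads,
                               library_sizes = sim$library_sizes)
  expect_equal(res$regions[order(res$regions$chrom, res$regions$start), -4],
               res2$regions[order(res2$regions$chrom, res2$regions$start), -4],
               ignore_attr = TRUE)
})
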