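test_that("feature assignment follows the midpoint and promoter-window rules", {
  ann <- tiny_annotation()
  # midpoint at gA's TSS
  a <- assign_nearest_feature(peak_df("chr1", 9950L, 10050L), ann)
  expect_equal(a$category, "promoter_tss")
  expect_equal(a$gene_id, "gA")
  expect_equal(a$dist_tss, 0)
  # midpoint exactly 1000 bp downstream (+ strand): closed window
  b <- assign_nearest_feature(peak_df("chr1", 10950L, 11050L), ann)
  expect_equal(b$category, "promoter_tss")
  expect_equal(b$dist_tss, 1000)
  # 1001 bp away: falls into the gene body instead
  b2 <- assign_nearest_feature(peak_df("chr1", 10951L, 11051L), ann)
  expect_equal(b2$category, "gene_body")
  # far from everything: intergenic
  c_ <- assign_nearest_feature(peak_df("chr1", 19950L, 20050L), ann)
  expect_equal(c_$category, "intergenic")
  # minus-strand gene gB (tss 30000, tes 26000): 500 bp genomically below
  # the TSS is downstream (+500) in transcription orientation
  d <- assign_nearest_feature(peak_df("chr1", 29450L, 29550L), ann)
  expect_equal(d$category, "promoter_tss")
  expect_equal(d$gene_id, "gB")
  expect_equal(d$dist_tss, 500)
  expect_error(assign_nearest_feature(peak_df("chr1", 1L, 2L),
                                      ann[integer(0), ]), "empty")
})

test_that("every peak gets exactly one category and counts sum to n", {
  g <- make_genome(n_chromosomes = 2L, chrom_length = 2e6, n_genes = 150L,
                   seed = 30)
  set.seed(31)
  st <- floor(runif(500, 0, 2e6 - 300))
  pk <- peak_df(sample(g$layout$chrom, 500, replace = TRUE), st, st + 300L)
  a <- assign_nearest_feature(pk, g$annotation)
  expect_equal(nrow(a), 500L)
  expect_true(all(a$category %in% c("promoter_tss", "tts", "gene_body",
                                    "intergenic")))
  expect_equal(sum(table(a$category)), 500L)
})

test_that("random-position enrichment is ~1 under uniform peaks", {
  g <- make_genome(n_chromosomes = 2L, chrom_length = 5e6, n_genes = 1000L,
                   seed = 3)
  set.seed(32)
  n <- 6000L
  ci <- sample(g$layout$chrom, n, replace = TRUE)
  st <- floor(runif(n, 0, 5e6 - 400))
  fe <- feature_enrichment(peak_df(ci, st, st + 400L), g$annotation,
                           g$layout, n_random = 30000L, seed = 33)
  expect_true(all(abs(fe$fold - 1) < 0.15))
  expect_error(feature_enrichment(peak_df(character(), integer(), integer()),
                                  g$annotation, g$layout), "no peaks")
})

test_that("enrichment is stable across seeds", {
  g <- make_genome(n_chromosomes = 1L, chrom_length = 5e6, n_genes = 500L,
                   seed = 40)
  sim <- simulate_peak_replicates(g, 300L, 100L, 0L, 0L, seed = 41)
  f1 <- feature_enrichment(sim$regions, g$annotation, g$layout,
                           n_random = 50000L, seed = 1)
  f2 <- feature_enrichment(sim$regions, g$annotation, g$layout,
                           n_random = 50000L, seed = 2)
  prom1 <- f1$fold[f1$category == "promoter_tss"]
  prom2 <- f2$fold[f2$category == "promoter_tss"]
  expect_lt(abs(prom1 - prom2) / prom1, 0.05)
})

test_that("TSS metaprofile is strand-aware and centered correctly", {
  ann <- tiny_annotation()
  # reads exactly at each TSS: the bin containing offset 0 is the maximum
  reads <- data.frame(chrom = ann$chrom, pos = ann$tss)
  prof <- tss_metaprofile(reads, ann, bin = 50L, window = 2000L)
  expect_equal(nrow(prof), 40L)
  expect_equal(prof$offset[which.max(prof$mean_occupancy)], 0L)
  # minus-strand gene: reads 100 bp below the TSS in genomic coordinates
  # are downstream, so they land in the +100 bin of the oriented profile
  gB <- ann[ann$gene_id == "gB", ]
  minus_reads <- data.frame(chrom = "chr1", pos = rep(gB$tss - 100L, 5L))
  prof2 <- tss_metaprofile(minus_reads, gB, bin = 50L, window = 2000L)
  expect_equal(prof2$offset[which.max(prof2$mean_occupancy)], 100L)
  # profile mass = reads in windows / n_genes / (total reads per million)
  expect_equal(sum(prof2$mean_occupancy), 5 / 1 / (5 / 1e6))
})

test_that("uniform reads give a flat metaprofile", {
  g <- make_genome(n_chromosomes = 1L, chrom_length = 2e6, n_genes = 100L,
                   seed = 50)
  set.seed(51)
  reads <- data.frame(chrom = "chr1", pos = floor(runif(4e5, 0, 2e6)))
  prof <- tss_metaprofile(reads, g$annotation, bin = 50L, window = 2000L)
  expect_lt(max(abs(prof$mean_occupancy / mean(prof$mean_occupancy) - 1)), 0.15)
})

test_that("genome coverage fraction is total peak width over genome length", {
  layout <- data.frame(chrom = "chr1", length = 1e6)
  expect_equal(genome_coverage_fraction(peak_df("chr1", 0L, 10000L), layout),
               0.01)
  expect_equal(genome_coverage_fraction(peak_df(character(), integer(),
                                                integer()), layout), 0)
  expect_equal(genome_coverage_fraction(peak_df("chr1", 0L, 1e6), layout), 1)
})
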