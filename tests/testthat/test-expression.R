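test_that("background filter applies the strict total-count rule", {
  cm <- rbind(g1 = c(3L, 3L, 3L), g2 = c(4L, 3L, 3L), g3 = c(0L, 0L, 0L))
  bg <- background_filter(cm, min_total = 10)
  expect_equal(bg$excluded, c("g1", "g3")) # 9 < 10 excluded, 10 kept
  expect_equal(bg$background, "g2")
  all_zero <- background_filter(rbind(a = c(0L, 0L), b = c(0L, 0L)))
  expect_length(all_zero$background, 0L)
  expect_setequal(all_zero$excluded, c("a", "b"))
})

test_that("identical groups give zero fold change and no calls", {
  cm <- matrix(rep(c(50L, 80L, 120L, 20L), each = 6L), nrow = 4L, byrow = TRUE)
  rownames(cm) <- paste0("g", 1:4)
  colnames(cm) <- paste0("s", 1:6)
  de <- nb_de_test(cm, rep(c("control", "mutant"), each = 3L))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$status == "ns"))
  expect_error(nb_de_test(cm, c("control", "mutant", "mutant", "mutant",
                                "mutant", "mutant")), ">= 2 samples")
})

test_that("status partition is exhaustive, exclusive and threshold-true", {
  sim <- simulate_counts(n_genes = 600L, de_fraction = 0.15, lfc = 2,
                         seed = 60)
  cm <- sim$counts[[1]]
  de <- nb_de_test(cm[background_filter(cm)$background, ],
                   sim$condition[[1]], alpha = 0.05, fc_threshold = 1.5)
  expect_true(all(de$status %in% c("up", "down", "ns")))
  up <- de$status == "up"
  down <- de$status == "down"
  expect_true(all(de$padj[up | down] < 0.05))
  expect_true(all(2^de$log2fc[up] > 1.5))
  expect_true(all(2^de$log2fc[down] < 1 / 1.5))
  ns <- de$status == "ns"
  expect_true(all(de$padj[ns] >= 0.05 | abs(de$log2fc[ns]) <= log2(1.5)))
  # BH monotonicity: padj non-decreasing in raw-p rank
  ord <- order(de$p)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
})

test_that("scaling one sample moves its size factor, not the fold changes", {
  sim <- simulate_counts(n_genes = 2000L, de_fraction = 0.1, lfc = 1.5,
                         lowly_expressed_fraction = 0, seed = 61)
  cm <- sim$counts[[1]]
  sf0 <- size_factors(cm)
  cm2 <- cm
  cm2[, 1] <- cm2[, 1] * 3L
  sf1 <- size_factors(cm2)
  # size factors are defined up to a common scale: the ratio to any other
  # sample's factor moves by exactly the multiplier
  expect_equal((sf1[1] / sf1[2]) / (sf0[1] / sf0[2]), 3, tolerance = 0.02,
               ignore_attr = TRUE)
  de0 <- nb_de_test(cm, sim$condition[[1]])
  de1 <- nb_de_test(cm2, sim$condition[[1]])
  expect_lt(mean(abs(de0$log2fc - de1$log2fc)), 0.05)
})

test_that("sample distance QC separates planted condition clusters", {
  sim <- simulate_counts(n_genes = 800L, de_fraction = 0.3, lfc = 2,
                         seed = 62)
  cm <- sim$counts[[1]]
  qc <- sample_distance_qc(cm)
  d <- qc$distance
  cond <- sim$condition[[1]]
  for (j in seq_len(ncol(cm))) {
    nn <- colnames(cm)[setdiff(order(d[j, ]), j)[1]]
    expect_equal(as.character(cond[match(nn, colnames(cm))]),
                 as.character(cond[j]))
  }
  # duplicated sample: zero distance, unit correlation
  cm_dup <- cbind(cm, dup = cm[, 1])
  qc2 <- sample_distance_qc(cm_dup)
  expect_equal(qc2$distance[1, "dup"], 0, ignore_attr = TRUE)
  expect_equal(qc2$correlation[1, "dup"], 1, ignore_attr = TRUE)
  # single-gene matrix: correlation omitted with a warning
  expect_warning(qc3 <- sample_distance_qc(cm[1, , drop = FALSE]),
                 "undefined")
  expect_null(qc3$correlation)
})
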