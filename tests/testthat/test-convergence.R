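test_that("hypergeometric tail matches subset enumeration on a literal case", {
  # N=10, K=4, n=5: enumerate all C(10,5)=252 draws directly
  draws <- utils::combn(10L, 5L, simplify = FALSE)
  p_enum <- mean(vapply(draws, function(s) sum(s <= 4L) >= 3L, TRUE))
  expect_equal(p_enum, 66 / 252)
  r <- overlap_result(K = 4L, n = 5L, k = 3L, N = 10L)
  expect_equal(r$p, p_enum, tolerance = 1e-12)
})

test_that("overlap result carries expected, fold, venn and bounds", {
  r <- overlap_result(K = 613L, n = 1123L, k = 119L, N = 15682L)
  expect_equal(r$expected, 613 * 1123 / 15682)
  expect_equal(round(r$fold, 1), 2.7)
  expect_equal(r$venn, c(A_only = 494L, shared = 119L, B_only = 1004L))
  expect_gt(r$p, 0)
  expect_lte(r$p, 1)
  full <- overlap_result(K = 20L, n = 20L, k = 20L, N = 20L)
  expect_equal(full$p, 1)
  expect_equal(full$fold, 1)
  expect_error(overlap_result(5L, 5L, 6L, 10L), "exceeds")
  expect_error(overlap_result(11L, 5L, 2L, 10L), "exceed")
})

test_that("p is non-increasing in k for fixed K, n, N", {
  for (cfg in list(c(20, 30, 100), c(5, 5, 12), c(50, 60, 200))) {
    K <- cfg[1]; n <- cfg[2]; N <- cfg[3]
    ks <- max(0, K + n - N):min(K, n)
    ps <- vapply(ks, function(k) overlap_result(K, n, k, N)$p, 1)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("set-based overlap handles universe policies", {
  A <- gene_set("a", c("g1", "g2", "g3"))
  B <- gene_set("b", c("g2", "g3", "g4"))
  U <- paste0("g", 1:10)
  r <- hypergeom_overlap(A, B, U)
  expect_equal(r$k, 2L)
  expect_equal(r$shared, c("g2", "g3"))
  expect_error(hypergeom_overlap(A, B, character()), "empty universe")
  expect_error(hypergeom_overlap(gene_set("a", c("g1", "zz")), B, U,
                                 mode = "strict"), "zz")
  expect_warning(r2 <- hypergeom_overlap(gene_set("a", c("g1", "zz")), B, U,
                                         mode = "lenient"), "added")
  expect_equal(r2$N, 11L)
  r3 <- suppressWarnings(hypergeom_overlap(gene_set("a", c("g1", "zz")), B, U,
                                           mode = "intersect"))
  expect_equal(r3$K, 1L)
})

test_that("target classification follows the activator/repressor rule", {
  de <- data.frame(gene_id = c("g1", "g3", "g4"),
                   status = c("down", "down", "up"),
                   stringsAsFactors = FALSE)
  act <- classify_targets("activator", c("g1", "g2"), de)
  expect_equal(act$gene_id[act$class == "potential_direct"], "g1")
  expect_setequal(act$gene_id[act$class == "potential_indirect"],
                  c("g3", "g4"))
  rep_ <- classify_targets("repressor", c("g1", "g2"), de)
  expect_length(rep_$gene_id[rep_$class == "potential_direct"], 0L)
  expect_setequal(rep_$gene_id[rep_$class == "potential_indirect"],
                  c("g1", "g3", "g4"))
  none <- classify_targets("activator", character(), de)
  expect_true(all(none$class == "potential_indirect"))
  expect_equal(nrow(act), 3L) # direct + indirect = all DE genes
})

test_that("directional breakdown conserves the shared-gene count", {
  mk <- function(ids, status) data.frame(gene_id = ids, status = status,
                                         stringsAsFactors = FALSE)
  deA <- mk(paste0("g", 1:6), c("up", "up", "down", "down", "ns", "up"))
  deB <- mk(paste0("g", 1:6), c("up", "down", "up", "down", "up", "ns"))
  bd <- directional_breakdown(deA, deB)
  expect_equal(sum(bd$table), bd$n_shared)
  expect_equal(bd$n_shared, 4L)
  expect_equal(bd$table["up", "up"], 1L)
  expect_equal(bd$table["up", "down"], 1L)
  expect_equal(bd$table["down", "up"], 1L)
  expect_equal(bd$table["down", "down"], 1L)
  all_up <- directional_breakdown(mk(c("a", "b"), c("up", "up")),
                                  mk(c("a", "b"), c("up", "up")))
  expect_equal(as.vector(all_up$table), c(2L, 0L, 0L, 0L))
  expect_warning(none <- directional_breakdown(mk("a", "up"), mk("b", "up")),
                 "no shared")
  expect_equal(sum(none$table), 0L)
  expect_true(is.na(none$fisher_p))
})

test_that("hub genes are the sorted intersection", {
  expect_equal(hub_genes(c("c", "a", "b"), c("b", "c", "d")), c("b", "c"))
  expect_length(hub_genes(c("a"), c("b")), 0L)
  expect_equal(hub_genes(c("b", "a"), c("a", "b")), c("a", "b"))
})

test_that("set enrichment corrects across collections and is null-calibrated", {
  U <- paste0("g", 1:500)
  query <- gene_set("q", U[1:50])
  ident <- set_enrichment(query, list(q = query), gene_set("u", U[1:50]))
  expect_equal(ident$p, 1)
  expect_equal(ident$fold, 1)
  disjoint <- set_enrichment(query, list(d = gene_set("d", U[51:100])), U)
  expect_equal(disjoint$k, 0L)
  expect_equal(disjoint$fold, 0)
  expect_equal(disjoint$p, 1)
  # null: random query vs 100 random collections, BH-significant ~ none
  set.seed(70)
  colls <- lapply(1:100, function(i) gene_set(paste0("c", i), sample(U, 40)))
  names(colls) <- paste0("c", 1:100)
  res <- set_enrichment(gene_set("q2", sample(U, 50)), colls, U)
  expect_lte(sum(res$padj < 0.05), 1L)
})
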