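# Hypergeometric overlap statistics, target classification, directional
# breakdowns, hub genes and generic gene-set enrichment.

as_members <- function(x, name) {
  if (inherits(x, "gene_set")) return(x$members)
  if (is.character(x)) return(unique(x))
  stop_data("'%s' must be a gene_set or a character vector", name)
}

#' Hypergeometric overlap of two gene sets
#'
#' Tests whether the overlap k between a set of size K and a set of size n
#' drawn from a universe of size N is larger than expected. The upper-tail
#' probability P(X >= k) is an exact log-gamma tail sum; fold enrichment
#' is k / (K n / N).
#'
#' @param setA,setB Gene sets (character vectors or [gene_set()] objects).
#' @param universe The background universe (character vector or gene_set).
#' @param mode How to treat query genes missing from the universe:
#'   `"lenient"` adds them with a warning, `"intersect"` drops them,
#'   `"strict"` errors listing the offending ids.
#' @return A list with class `overlap_result`: `K`, `n`, `k`, `N`,
#'   `expected`, `fold`, `p`, `venn` (A_only, shared, B_only) and the
#'   shared member ids.
#' @export
hypergeom_overlap <- function(setA, setB, universe,
                              mode = c("lenient", "intersect", "strict")) {
  mode <- match.arg(mode)
  A <- as_members(setA, "setA")
  B <- as_members(setB, "setB")
  U <- as_members(universe, "universe")
  if (length(U) == 0L)
    stop_data("empty universe")
  missing <- setdiff(union(A, B), U)
  if (length(missing)) {
    if (mode == "strict")
      stop_data("query ids absent from the universe: %s",
                paste(utils::head(missing, 10L), collapse = ", "))
    if (mode == "lenient") {
      warning(sprintf("%d query id(s) absent from the universe were added to it",
                      length(missing)), call. = FALSE)
      U <- c(U, missing)
    } else {
      A <- intersect(A, U)
      B <- intersect(B, U)
    }
  }
  shared <- intersect(A, B)
  overlap_result(K = length(A), n = length(B), k = length(shared),
                 N = length(U), shared = sort(shared))
}

#' Hypergeometric overlap from the four counts
#'
#' @param K,n Sizes of the two sets.
#' @param k Observed overlap.
#' @param N Universe size.
#' @param shared Optional shared member ids (bookkeeping only).
#' @return An `overlap_result` (see [hypergeom_overlap()]).
#' @export
overlap_result <- function(K, n, k, N, shared = NULL) {
  K <- check_count(K, "K"); n <- check_count(n, "n")
  k <- check_count(k, "k"); N <- check_count(N, "N", min = 1L)
  if (K > N || n > N) stop_data("set sizes exceed the universe (K=%d, n=%d, N=%d)", K, n, N)
  if (k > min(K, n)) stop_data("overlap k=%d exceeds min(K, n)", k)
  if (k < K + n - N) stop_data("overlap k=%d below the forced minimum K+n-N", k)
  expected <- K * n / N
  structure(list(
    K = K, n = n, k = k, N = N,
    expected = expected,
    fold = if (expected > 0) k / expected else NA_real_,
    p = phyper_upper(k, K, n, N),
    venn = c(A_only = K - k, shared = k, B_only = n - k),
    shared = shared
  ), class = "overlap_result")
}

# Exact upper tail P(X >= k) for X ~ Hypergeometric(N, K, n), summed in
# log space via lgamma to stay accurate for extreme enrichments.
phyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  min(exp(m + log(sum(exp(log_terms - m)))), 1)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: k = %d of K = %d vs n = %d in N = %d\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("expected = %.2f, fold = %.2f, P(X >= k) = %.3g\n",
              x$expected, x$fold, x$p))
  invisible(x)
}

#' Classify DE genes as potentially direct or indirect targets
#'
#' For an activator, direct targets are evidence-carrying genes (e.g.
#' promoter-bound) that are downregulated when the factor is lost; for a
#' repressor, evidence-carrying genes (e.g. repressive-mark loss) that are
#' upregulated. All other differentially expressed genes are potentially
#' indirect.
#'
#' @param factor_mode `"activator"` or `"repressor"`.
#' @param evidence Gene set carrying the factor's physical evidence.
#' @param de A DE table from [nb_de_test()] (or any data.frame with
#'   `gene_id` and `status` in up/down/ns).
#' @return A data.frame `gene_id`, `class`
#'   (potential_direct / potential_indirect), one row per DE gene.
#' @export
classify_targets <- function(factor_mode = c("activator", "repressor"),
                             evidence, de) {
  factor_mode <- match.arg(factor_mode)
  ev <- as_members(evidence, "evidence")
  up <- de$gene_id[de$status == "up"]
  down <- de$gene_id[de$status == "down"]
  direct <- intersect(ev, if (factor_mode == "activator") down else up)
  de_genes <- c(up, down)
  data.frame(
    gene_id = de_genes,
    class = ifelse(de_genes %in% direct, "potential_direct",
                   "potential_indirect"),
    stringsAsFactors = FALSE
  )
}

#' Directional breakdown of shared DE genes
#'
#' Cross-tabulates the direction of change of genes differentially
#' expressed in both contrasts and tests the 2x2 table for independence
#' of directions with a two-sided Fisher exact test.
#'
#' @param deA,deB DE tables (`gene_id`, `status`).
#' @return List: `table` (2x2 matrix, rows = direction in A, cols =
#'   direction in B), `n_shared`, `fisher_p` (NA with a warning when no
#'   genes are shared), `fold` (per-cell observed/expected under
#'   independence), `genes` (data.frame gene_id, dir_a, dir_b).
#' @export
directional_breakdown <- function(deA, deB) {
  sigA <- deA[deA$status %in% c("up", "down"), ]
  sigB <- deB[deB$status %in% c("up", "down"), ]
  shared <- intersect(sigA$gene_id, sigB$gene_id)
  dir_a <- factor(sigA$status[match(shared, sigA$gene_id)],
                  levels = c("up", "down"))
  dir_b <- factor(sigB$status[match(shared, sigB$gene_id)],
                  levels = c("up", "down"))
  tab <- table(A = dir_a, B = dir_b)
  tab <- matrix(as.integer(tab), 2L, 2L,
                dimnames = list(A = c("up", "down"), B = c("up", "down")))
  if (length(shared) == 0L) {
    warning("no shared DE genes: directional enrichment undefined",
            call. = FALSE)
    fp <- NA_real_
    fold_cells <- matrix(NA_real_, 2L, 2L, dimnames = dimnames(tab))
  } else {
    fp <- stats::fisher.test(tab)$p.value
    expected_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    fold_cells <- ifelse(expected_cells > 0, tab / expected_cells, NA_real_)
  }
  stopifnot(sum(tab) == length(shared)) # conservation of shared genes
  list(table = tab, n_shared = length(shared), fisher_p = fp,
       fold = fold_cells,
       genes = data.frame(gene_id = shared, dir_a = as.character(dir_a),
                          dir_b = as.character(dir_b),
                          stringsAsFactors = FALSE))
}

#' Hub genes: intersection of shared genomic targets and shared DE genes
#'
#' @param genomic_overlap Genes bound/marked by both factors.
#' @param de_overlap Genes differentially expressed in both contrasts.
#' @return Sorted character vector of hub gene ids.
#' @export
hub_genes <- function(genomic_overlap, de_overlap) {
  sort(intersect(as_members(genomic_overlap, "genomic_overlap"),
                 as_members(de_overlap, "de_overlap")))
}

#' Gene-set enrichment of a query against a collection
#'
#' One hypergeometric overlap test per collection set against the stated
#' universe, with multiplicity correction across collections.
#'
#' @param query Query gene set.
#' @param collections Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background universe.
#' @param correction `"BH"`, `"bonferroni"` or `"none"`.
#' @param mode Universe policy passed to [hypergeom_overlap()].
#' @return A data.frame `label`, `K`, `n`, `k`, `N`, `expected`, `fold`,
#'   `p`, `padj`, ordered by `p`.
#' @export
set_enrichment <- function(query, collections, universe,
                           correction = c("BH", "bonferroni", "none"),
                           mode = "lenient") {
  correction <- match.arg(correction)
  if (length(collections) == 0L)
    stop_data("empty collection list")
  rows <- lapply(seq_along(collections), function(i) {
    r <- hypergeom_overlap(query, collections[[i]], universe, mode = mode)
    data.frame(label = names(collections)[i] %||% as.character(i),
               K = r$K, n = r$n, k = r$k, N = r$N, expected = r$expected,
               fold = r$fold, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = if (correction == "none")
    "none" else if (correction == "BH") "BH" else "bonferroni")
  out[order(out$p), , drop = FALSE]
}
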