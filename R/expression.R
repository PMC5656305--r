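# Background filtering and a minimal negative-binomial two-group
# differential-expression test.
#
# The test is a deliberately small NB stage: median-of-ratios size
# factors, method-of-moments gene-wise dispersion shrunk toward a
# parametric mean-dispersion trend (equal-weights average), and a Wald
# test on the log2 fold change with BH adjustment. It shares threshold
# semantics (padj < alpha, fold change > fc) with the full GLM machinery
# of dedicated DE packages but claims no numerical equivalence with them.

#' Background filter on total raw counts
#'
#' A gene is excluded when its total raw count across all samples of the
#' experiment is strictly below `min_total`.
#'
#' @param counts Integer matrix, genes x samples.
#' @param min_total Threshold in reads.
#' @return List with `background` and `excluded` gene-id vectors.
#' @export
background_filter <- function(counts, min_total = 10) {
  if (is.null(dim(counts)) || nrow(counts) == 0L)
    stop_data("count matrix is empty")
  total <- rowSums(counts)
  excluded <- total < min_total
  list(background = rownames(counts)[!excluded],
       excluded = rownames(counts)[excluded])
}

#' Median-of-ratios size factors
#'
#' @param counts Count matrix, genes x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  ok <- is.finite(log_geo)
  if (!any(ok)) {
    # no gene expressed in every sample: fall back to total-count scaling
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  apply(counts, 2L, function(col)
    exp(stats::median(log(col[ok]) - log_geo[ok])))
}

#' Minimal negative-binomial two-group differential expression test
#'
#' @param counts Count matrix, genes x samples (apply
#'   [background_filter()] first).
#' @param condition Factor/character per sample with two levels; the first
#'   level is the reference (control), fold changes are second vs first.
#' @param alpha Adjusted-p significance threshold.
#' @param fc_threshold Fold-change threshold applied two-sided: `up` if
#'   `2^log2fc > fc_threshold`, `down` if `2^log2fc < 1/fc_threshold`.
#' @return A data.frame `gene_id`, `base_mean`, `log2fc`, `lfc_se`,
#'   `dispersion`, `p`, `padj`, `status` (up/down/ns).
#' @export
nb_de_test <- function(counts, condition, alpha = 0.05, fc_threshold = 1.5) {
  check_proportion(alpha, "alpha", strict = TRUE)
  check_number(fc_threshold, "fc_threshold", lower = 1, strict_lower = TRUE)
  condition <- factor(condition)
  if (nlevels(condition) != 2L)
    stop_data("condition must have exactly two levels")
  if (length(condition) != ncol(counts))
    stop_data("one condition label per sample required")
  if (any(table(condition) < 2L))
    stop_data("each condition needs >= 2 samples")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, `/`)
  g1 <- condition == levels(condition)[1L]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  base_mean <- rowMeans(norm)

  row_var <- function(x) {
    mu <- rowMeans(x)
    rowSums((x - mu)^2) / (ncol(x) - 1L)
  }
  v1 <- row_var(norm[, g1, drop = FALSE])
  v2 <- row_var(norm[, g2, drop = FALSE])
  df_tot <- n1 + n2 - 2L
  v_pooled <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df_tot
  wm <- ((n1 - 1L) * m1 + (n2 - 1L) * m2) / df_tot
  wm2 <- ((n1 - 1L) * m1^2 + (n2 - 1L) * m2^2) / df_tot
  # var = mu + d mu^2  =>  method-of-moments dispersion
  disp_gene <- ifelse(wm2 > 0, (v_pooled - wm) / wm2, NA_real_)
  disp_gene <- pmax(disp_gene, 1e-8)

  # parametric trend d(mu) = a0 + a1/mu, fitted on moderately expressed genes
  fit_ok <- which(is.finite(disp_gene) & base_mean >= 1 & disp_gene > 1e-8)
  a0 <- 0; a1 <- 0
  if (length(fit_ok) >= 10L) {
    co <- stats::coef(stats::lm(disp_gene[fit_ok] ~ I(1 / base_mean[fit_ok])))
    a0 <- max(co[1L], 1e-8)
    a1 <- max(co[2L], 0)
  } else {
    a0 <- max(stats::median(disp_gene, na.rm = TRUE), 1e-8)
  }
  disp_trend <- pmax(a0 + a1 / pmax(base_mean, 1e-8), 1e-8)
  dispersion <- (ifelse(is.na(disp_gene), disp_trend, disp_gene) + disp_trend) / 2

  eps <- 0.5 # pseudo-mean keeps the log ratio finite at zero counts
  log2fc <- log2((m2 + eps) / (m1 + eps))
  inv_sf1 <- mean(1 / sf[g1]); inv_sf2 <- mean(1 / sf[g2])
  var_m1 <- (m1 * inv_sf1 + dispersion * m1^2) / n1
  var_m2 <- (m2 * inv_sf2 + dispersion * m2^2) / n2
  se <- sqrt(var_m1 / (m1 + eps)^2 + var_m2 / (m2 + eps)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  # Wald statistic against a small-sample t reference: the equal-weights
  # shrinkage toward a trend fitted on thousands of genes quarters the
  # variance of the dispersion estimate, so the effective df is about four
  # times the residual df. A normal reference is anticonservative in the
  # far tail at 2-3 replicates per group.
  df_eff <- 4L * df_tot
  p <- 2 * stats::pt(-abs(z), df = df_eff)
  p[m1 == 0 & m2 == 0] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  fc <- 2^log2fc
  status <- ifelse(padj < alpha & fc > fc_threshold, "up",
            ifelse(padj < alpha & fc < 1 / fc_threshold, "down", "ns"))
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, lfc_se = se, dispersion = dispersion,
             p = p, padj = padj, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample distance and correlation QC
#'
#' Computes Euclidean distances and Pearson correlations between samples
#' on `log2(normalized count + 1)` values (a simple variance-flattening
#' transform) and returns the average-linkage dendrogram order.
#'
#' @param counts Count matrix, genes x samples (>= 2 samples).
#' @return List: `distance` (sample x sample matrix), `correlation`
#'   (matrix, or NULL with a warning for a single-gene matrix), `order`
#'   (sample ids in dendrogram order), `transformed` (the log matrix).
#' @export
sample_distance_qc <- function(counts) {
  if (ncol(counts) < 2L)
    stop_data("need >= 2 samples")
  sf <- size_factors(counts)
  lt <- log2(sweep(counts, 2L, sf, `/`) + 1)
  d <- as.matrix(stats::dist(t(lt)))
  corr <- NULL
  if (nrow(lt) < 2L) {
    warning("correlation undefined for a single-gene matrix; omitted",
            call. = FALSE)
  } else {
    corr <- suppressWarnings(stats::cor(lt, method = "pearson"))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(distance = d, correlation = corr,
       order = colnames(counts)[hc$order], transformed = lt)
}
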