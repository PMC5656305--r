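# qPCR arithmetic: delta-delta-Ct relative expression with one or more
# reference genes, and ChIP-qPCR percent-input fold enrichment over
# negative control regions.

#' Delta-delta-Ct fold changes with multiple reference genes
#'
#' Per condition, delta-Ct is the mean target Ct minus the mean (over
#' reference genes) of each reference's mean Ct; combining references by
#' arithmetic mean on the Ct scale equals their geometric mean on the
#' expression scale. Fold change of each condition versus the control is
#' `2^-(ddCt)`.
#'
#' @param measurements Data.frame with columns `condition`, `gene`, `ct`
#'   (technical replicates as rows; all Ct > 0).
#' @param target Target gene name.
#' @param reference_genes Character vector of reference gene names.
#' @param control Name of the control condition.
#' @return A data.frame `condition`, `delta_ct`, `ddct`, `fold` (control
#'   row included with fold = 1).
#' @export
ddct_fold_change <- function(measurements, target, reference_genes,
                             control = "control") {
  need <- c("condition", "gene", "ct")
  if (!all(need %in% names(measurements)))
    stop_data("measurements must have columns %s", paste(need, collapse = ", "))
  if (any(measurements$ct <= 0))
    stop_data("all Ct values must be positive")
  conds <- unique(measurements$condition)
  if (!(control %in% conds))
    stop_data("control condition '%s' missing from the measurements", control)
  if (length(reference_genes) < 1L)
    stop_data("at least one reference gene is required")
  mean_ct <- function(cond, gene) {
    x <- measurements$ct[measurements$condition == cond &
                           measurements$gene == gene]
    if (length(x) == 0L)
      stop_data("no Ct replicates for gene '%s' in condition '%s'", gene, cond)
    mean(x)
  }
  delta_ct <- vapply(conds, function(cond) {
    mean_ct(cond, target) -
      mean(vapply(reference_genes, function(r) mean_ct(cond, r), 1))
  }, 1)
  ddct <- delta_ct - delta_ct[conds == control]
  data.frame(condition = conds, delta_ct = unname(delta_ct),
             ddct = unname(ddct), fold = unname(2^(-ddct)),
             stringsAsFactors = FALSE)
}

#' Percent input from ChIP and input Ct values
#'
#' `100 * input_fraction * 2^(Ct_input - Ct_IP)`: the input Ct is adjusted
#' for the fraction of chromatin it represents, so adding a constant to
#' every Ct leaves the result unchanged.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input sample.
#' @param input_fraction Fraction of chromatin used as input (default 1%).
#' @return Percent input.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  check_number(input_fraction, "input_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  100 * input_fraction * 2^(ct_input - ct_ip)
}

#' ChIP-qPCR fold enrichment over two negative regions
#'
#' Fold enrichment of a positive region is its percent input divided by
#' the mean percent input of the negative control regions.
#'
#' @param positive Percent-input value(s) of the positive region
#'   (replicates averaged).
#' @param negatives Numeric vector (typically length 2) of the negative
#'   regions' percent-input values, or a list of replicate vectors
#'   (each averaged first).
#' @return Fold enrichment.
#' @export
chip_qpcr_enrichment <- function(positive, negatives) {
  if (is.list(negatives)) negatives <- vapply(negatives, mean, 1)
  pos <- mean(positive)
  if (any(negatives <= 0) || pos <= 0)
    stop_data("percent-input values must be positive")
  pos / mean(negatives)
}
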