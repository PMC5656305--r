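# Shared fixtures, built in code.

tiny_annotation <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(10000L, 30000L, 5000L),
    tes = c(14000L, 26000L, 9000L),
    stringsAsFactors = FALSE
  )
}

tiny_layout <- function() {
  data.frame(chrom = c("chr1", "chr2"), length = c(50000L, 20000L),
             stringsAsFactors = FALSE)
}

peak_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# map merged regions back to the simulator's planted regions (1:1 overlap)
match_truth <- function(pipeline_res, sim) {
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(pipeline_res$regions$chrom,
      IRanges::IRanges(pipeline_res$regions$start + 1L, pipeline_res$regions$end)),
    GenomicRanges::GRanges(sim$regions$chrom,
      IRanges::IRanges(sim$regions$start + 1L, sim$regions$end)))
  stopifnot(length(hits) == nrow(pipeline_res$regions))
  data.frame(
    name = pipeline_res$regions$name,
    status = sim$truth$status[S4Vectors::subjectHits(hits)],
    class = sim$truth$class[S4Vectors::subjectHits(hits)],
    kept = pipeline_res$regions$name %in% pipeline_res$kept$name,
    stringsAsFactors = FALSE
  )
}

# counting-based hypergeometric upper tail: exact integer combinatorics,
# independent of the package's log-gamma tail sum
hyper_tail_by_counting <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
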