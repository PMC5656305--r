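# Replicate-concordance filtering of ChIP peak calls.
#
# Cascade: merge the two replicates' peak calls, count reads per merged
# region in each replicate, normalize to library size, then keep regions
# with mean normalized reads > min_mean and replicate ratio < max_ratio
# (both strict). An optional k-means profile-clustering QC flags clusters
# with depleted signal around the peak center.

#' Concordance filter thresholds
#'
#' @param min_mean Minimum mean normalized read count (strict; regions
#'   with mean exactly at the threshold are rejected).
#' @param max_ratio Maximum replicate ratio (strict).
#' @return A validated list with class `concordance_thresholds`.
#' @export
concordance_thresholds <- function(min_mean = 100, max_ratio = 2) {
  check_number(min_mean, "min_mean", lower = 0)
  check_number(max_ratio, "max_ratio", lower = 1, strict_lower = TRUE)
  structure(list(min_mean = min_mean, max_ratio = max_ratio),
            class = "concordance_thresholds")
}

#' Merge two replicates' peak intervals
#'
#' Returns the union of both interval sets as disjoint intervals sorted by
#' (chrom, start). Overlapping and book-ended intervals are merged.
#'
#' @param peaks_rep1,peaks_rep2 Peak data.frames (`chrom`, `start`, `end`;
#'   0-based half-open). Either may be empty.
#' @return A data.frame `chrom`, `start`, `end`, `name`.
#' @export
merge_regions <- function(peaks_rep1, peaks_rep2) {
  both <- rbind(peaks_rep1[c("chrom", "start", "end")],
                peaks_rep2[c("chrom", "start", "end")])
  if (nrow(both) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  gr <- peaks_to_granges(both)
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  out <- granges_to_peaks(merged)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out$name <- sprintf("region_%04d", seq_len(nrow(out)))
  out
}

#' Count reads into disjoint regions
#'
#' A read is a single 5' position; it is counted into the (at most one)
#' region whose half-open interval contains it.
#'
#' @param regions Disjoint region data.frame (`chrom`, `start`, `end`).
#' @param reads A data.frame (`chrom`, `pos`) or a named list of them,
#'   one per sample.
#' @return An integer matrix, regions x samples.
#' @export
count_reads_in_regions <- function(regions, reads) {
  if (is.data.frame(reads)) reads <- list(sample = reads)
  gr <- peaks_to_granges(regions)
  if (length(gr) > 1L && any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    stop_data("regions must be disjoint; run merge_regions() first")
  counts <- vapply(reads, function(rd) {
    if (nrow(rd) == 0L) return(integer(nrow(regions)))
    pts <- GenomicRanges::GRanges(rd$chrom,
                                  IRanges::IRanges(rd$pos + 1L, width = 1L))
    GenomicRanges::countOverlaps(gr, pts)
  }, integer(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions),
                   dimnames = list(regions$name, names(reads)))
  counts
}

#' Normalize raw region counts to library size
#'
#' Each sample's counts are rescaled by (mean library size / that sample's
#' library size), keeping values on a reads-like scale so that read-count
#' thresholds remain meaningful. Equal library sizes leave counts
#' unchanged.
#'
#' @param raw Numeric matrix (regions x samples) or vector per sample.
#' @param library_sizes Positive numeric vector, one per sample.
#' @return Matrix of normalized counts, same shape as `raw`.
#' @export
normalize_to_library_size <- function(raw, library_sizes) {
  raw <- as.matrix(raw)
  if (length(library_sizes) != ncol(raw))
    stop_data("need one library size per sample (%d != %d)",
              length(library_sizes), ncol(raw))
  if (any(library_sizes <= 0))
    stop_data("library sizes must be positive")
  scale <- mean(library_sizes) / library_sizes
  sweep(raw, 2L, scale, `*`)
}

#' Apply the replicate-concordance filter
#'
#' Keeps regions with mean normalized count strictly above
#' `thresholds$min_mean` and replicate ratio strictly below
#' `thresholds$max_ratio`. The ratio is max/min of the two normalized
#' counts; with exactly one zero count it is infinite (rejected as
#' `high_ratio`), with both zero it is undefined and the region is
#' rejected as `low_mean`.
#'
#' @param peaks Data.frame with columns `norm_rep1`, `norm_rep2` (plus any
#'   identifier columns, carried through).
#' @param thresholds A [concordance_thresholds()] object.
#' @return List with elements `kept` and `rejected`; both carry `mean_norm`,
#'   `ratio` and `qc_flags` columns (comma-separated flags, empty when kept).
#' @export
concordance_filter <- function(peaks, thresholds = concordance_thresholds()) {
  stopifnot(inherits(thresholds, "concordance_thresholds"))
  if (!all(c("norm_rep1", "norm_rep2") %in% names(peaks)))
    stop_data("peaks must carry normalized counts 'norm_rep1', 'norm_rep2'")
  a <- peaks$norm_rep1
  b <- peaks$norm_rep2
  mean_norm <- (a + b) / 2
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  ratio <- ifelse(hi == 0, NA_real_, hi / lo) # both zero -> undefined
  low_mean <- !(mean_norm > thresholds$min_mean)
  high_ratio <- !is.na(ratio) & !(ratio < thresholds$max_ratio)
  bad_cluster <- if (!is.null(peaks$bad_cluster)) peaks$bad_cluster else
    rep(FALSE, nrow(peaks))
  flag_parts <- cbind(ifelse(low_mean, "low_mean", ""),
                      ifelse(high_ratio, "high_ratio", ""),
                      ifelse(bad_cluster, "bad_cluster", ""))
  flags <- apply(flag_parts, 1L, function(p) paste(p[nzchar(p)], collapse = ","))
  if (nrow(peaks) == 0L) flags <- character()
  peaks$mean_norm <- mean_norm
  peaks$ratio <- ratio
  peaks$qc_flags <- flags
  keep <- !low_mean & !high_ratio & !bad_cluster
  list(kept = peaks[keep, , drop = FALSE],
       rejected = peaks[!keep, , drop = FALSE])
}

#' k-means profile clustering QC
#'
#' Represents each peak by its binned read-intensity profile in a window
#' around its midpoint, clusters the profiles with k-means, and flags
#' clusters whose mean center intensity falls below `flag_fraction` of the
#' global mean center intensity (an automated stand-in for the visual
#' inspection of cluster heatmaps).
#'
#' @param peaks Region data.frame (`chrom`, `start`, `end`).
#' @param reads Read positions (data.frame or list of data.frames; pooled).
#' @param k Number of clusters (>= 2, <= number of peaks).
#' @param bin Bin width in bp.
#' @param window Profile window in bp (multiple of `bin`).
#' @param flag_fraction Flag threshold relative to the global mean center
#'   intensity.
#' @param seed Integer seed for k-means initialization.
#' @return List: `cluster` (integer label per peak), `flagged_clusters`,
#'   `bad_cluster` (logical per peak), `profiles` (peaks x bins matrix).
#' @export
cluster_qc <- function(peaks, reads, k = 8L, bin = 50L, window = 2000L,
                       flag_fraction = 0.25, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  if (k > nrow(peaks))
    stop_data("k = %d exceeds the number of peaks (%d)", k, nrow(peaks))
  if (window %% bin != 0L)
    stop_data("window (%d) must be a multiple of bin (%d)", window, bin)
  if (is.data.frame(reads)) reads <- list(reads)
  rd <- do.call(rbind, lapply(reads, function(x) x[c("chrom", "pos")]))
  nb <- window %/% bin
  mid <- floor((peaks$start + peaks$end) / 2)
  win <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(mid - window %/% 2L + 1L,
                                                 width = window))
  prof <- matrix(0, nrow(peaks), nb)
  if (nrow(rd) > 0L) {
    pts <- GenomicRanges::GRanges(rd$chrom,
                                  IRanges::IRanges(rd$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(win, pts)
    off <- rd$pos[S4Vectors::subjectHits(hits)] -
      (mid[S4Vectors::queryHits(hits)] - window %/% 2L)
    bidx <- off %/% bin + 1L
    tab <- table(factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(peaks))),
                 factor(bidx, levels = seq_len(nb)))
    prof <- matrix(as.numeric(tab), nrow(peaks), nb)
  }
  set.seed(derive_seed(seed, 71L))
  n_distinct <- nrow(unique(prof))
  if (n_distinct < k) {
    # fewer distinct profiles than clusters: every profile is its own center
    cluster <- as.integer(factor(apply(prof, 1L, paste, collapse = ",")))
    km <- list(cluster = cluster)
  } else {
    km <- stats::kmeans(prof, centers = k, nstart = 5L, iter.max = 50L)
  }
  center_bins <- c(nb %/% 2L, nb %/% 2L + 1L) # the two bins flanking offset 0
  center_int <- rowMeans(prof[, center_bins, drop = FALSE])
  global <- mean(center_int)
  cl_means <- tapply(center_int, km$cluster, mean)
  flagged <- as.integer(names(cl_means)[cl_means < flag_fraction * global])
  list(cluster = km$cluster,
       flagged_clusters = flagged,
       bad_cluster = km$cluster %in% flagged,
       profiles = prof)
}

#' Run the full concordance cascade on two replicate call sets
#'
#' Merge, count, normalize, optionally cluster-QC, then filter.
#'
#' @param peaks_rep1,peaks_rep2 Per-replicate peak calls.
#' @param reads Named list of two read-position data.frames.
#' @param library_sizes Two library sizes (defaults to read totals).
#' @param thresholds A [concordance_thresholds()] object.
#' @param exclude_chroms Chromosomes dropped before filtering.
#' @param cluster_k If non-NULL, run [cluster_qc()] with this k.
#' @param seed Seed for the clustering stage.
#' @return List: `regions` (merged, with counts, mean, ratio, flags),
#'   `kept`, `rejected`.
#' @export
concordance_pipeline <- function(peaks_rep1, peaks_rep2, reads,
                                 library_sizes = NULL,
                                 thresholds = concordance_thresholds(),
                                 exclude_chroms = character(),
                                 cluster_k = NULL, seed = 1L) {
  merged <- merge_regions(peaks_rep1, peaks_rep2)
  if (length(exclude_chroms))
    merged <- merged[!(merged$chrom %in% exclude_chroms), , drop = FALSE]
  raw <- count_reads_in_regions(merged, reads)
  if (is.null(library_sizes))
    library_sizes <- vapply(reads, nrow, 1L)
  norm <- normalize_to_library_size(raw, library_sizes)
  merged$raw_rep1 <- raw[, 1L]
  merged$raw_rep2 <- raw[, 2L]
  merged$norm_rep1 <- norm[, 1L]
  merged$norm_rep2 <- norm[, 2L]
  if (!is.null(cluster_k)) {
    cq <- cluster_qc(merged, reads, k = cluster_k, seed = seed)
    merged$cluster <- cq$cluster
    merged$bad_cluster <- cq$bad_cluster
  }
  res <- concordance_filter(merged, thresholds)
  regions <- rbind(res$kept, res$rejected)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  c(list(regions = regions), res)
}
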