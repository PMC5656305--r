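# Peak-to-feature assignment, random-position fold enrichment, TSS
# metaprofiles and genome coverage.
#
# Assignment is midpoint-based: a peak whose midpoint lies within the
# closed +/- promoter_halfwidth window of any TSS is a promoter peak of
# the nearest such gene. With TSS/TES-only annotation the remaining
# categories are tts (near a transcription end site), gene_body and
# intergenic.

#' Assign peaks to genomic features
#'
#' @param peaks Peak data.frame (`chrom`, `start`, `end`, optional `name`).
#' @param annotation Gene annotation (see [read_annotation()]).
#' @param promoter_halfwidth Closed promoter window half-width around the
#'   TSS, in bp.
#' @param tts_halfwidth Closed window half-width around the TES for the
#'   `tts` category.
#' @return A data.frame `peak_id`, `category` (promoter_tss / tts /
#'   gene_body / intergenic), `gene_id` (nearest gene), `dist_tss` (signed
#'   bp in transcription orientation; negative = upstream of the TSS).
#' @export
assign_nearest_feature <- function(peaks, annotation,
                                   promoter_halfwidth = 1000L,
                                   tts_halfwidth = 1000L) {
  if (is.null(annotation) || nrow(annotation) == 0L)
    stop_data("annotation is empty; feature assignment is undefined")
  if (nrow(peaks) == 0L)
    return(data.frame(peak_id = character(), category = character(),
                      gene_id = character(), dist_tss = numeric(),
                      stringsAsFactors = FALSE))
  mid <- floor((peaks$start + peaks$end) / 2)
  peak_id <- if (!is.null(peaks$name)) peaks$name else
    sprintf("peak_%04d", seq_len(nrow(peaks)))

  # nearest gene by |midpoint - TSS| per chromosome; ties to the
  # lexicographically smallest gene_id
  nearest_site <- function(site_pos) {
    gene_idx <- rep(NA_integer_, length(mid))
    for (ch in unique(peaks$chrom)) {
      gsel <- which(annotation$chrom == ch)
      psel <- which(peaks$chrom == ch)
      if (length(gsel) == 0L || length(psel) == 0L) next
      ord <- order(site_pos[gsel], annotation$gene_id[gsel])
      gsel <- gsel[ord]
      pos <- site_pos[gsel]
      iv <- findInterval(mid[psel], pos)
      lo <- pmax(iv, 1L)
      hi <- pmin(iv + 1L, length(pos))
      d_lo <- abs(mid[psel] - pos[lo])
      d_hi <- abs(mid[psel] - pos[hi])
      pick <- ifelse(d_hi < d_lo, hi,
              ifelse(d_lo < d_hi, lo,
                     # equidistant: smaller gene_id wins
                     ifelse(annotation$gene_id[gsel[lo]] <=
                              annotation$gene_id[gsel[hi]], lo, hi)))
      gene_idx[psel] <- gsel[pick]
    }
    gene_idx
  }
  tss_gene <- nearest_site(annotation$tss)
  tes_gene <- nearest_site(annotation$tes)

  no_gene_chrom <- is.na(tss_gene)
  dist_tss_genomic <- ifelse(no_gene_chrom, NA_real_,
                             mid - annotation$tss[tss_gene])
  dist_tes_genomic <- ifelse(is.na(tes_gene), NA_real_,
                             mid - annotation$tes[tes_gene])

  in_promoter <- !is.na(dist_tss_genomic) &
    abs(dist_tss_genomic) <= promoter_halfwidth
  in_tts <- !is.na(dist_tes_genomic) &
    abs(dist_tes_genomic) <= tts_halfwidth

  # gene-body containment via interval overlap on the full gene extent
  body <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmin(annotation$tss, annotation$tes) + 1L,
                     pmax(annotation$tss, annotation$tes) + 1L)
  )
  pts <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(pts, body)
  body_gene <- rep(NA_integer_, length(mid))
  if (length(hits)) {
    h <- as.data.frame(hits)
    h$gid <- annotation$gene_id[h$subjectHits]
    h <- h[order(h$queryHits, h$gid), ]
    h <- h[!duplicated(h$queryHits), ]
    body_gene[h$queryHits] <- h$subjectHits
  }

  category <- ifelse(in_promoter, "promoter_tss",
              ifelse(in_tts, "tts",
              ifelse(!is.na(body_gene), "gene_body", "intergenic")))
  category[no_gene_chrom & is.na(body_gene)] <- "intergenic"
  gene_idx <- ifelse(in_promoter, tss_gene,
              ifelse(in_tts, tes_gene,
              ifelse(!is.na(body_gene), body_gene, tss_gene)))

  minus <- !is.na(gene_idx) & annotation$strand[gene_idx] == "-"
  dist_oriented <- mid - ifelse(is.na(gene_idx), NA_real_,
                                annotation$tss[gene_idx])
  dist_oriented[minus] <- -dist_oriented[minus]

  data.frame(peak_id = peak_id,
             category = category,
             gene_id = ifelse(is.na(gene_idx), NA_character_,
                              annotation$gene_id[gene_idx]),
             dist_tss = dist_oriented,
             stringsAsFactors = FALSE)
}

#' Unique genes with a promoter-associated peak
#' @param assignments Output of [assign_nearest_feature()].
#' @return Sorted character vector of gene ids.
#' @export
promoter_genes <- function(assignments) {
  sort(unique(assignments$gene_id[assignments$category == "promoter_tss"]))
}

#' Fold enrichment of peak categories over random genomic positions
#'
#' Samples `n_random` positions uniformly over the genome with the same
#' width distribution as the observed peaks, assigns them with the same
#' rules, and reports observed/random category fractions and their ratio.
#'
#' @param peaks Peak data.frame.
#' @param annotation Gene annotation.
#' @param layout Genome layout data.frame (`chrom`, `length`).
#' @param n_random Number of random positions (>= number of peaks).
#' @param promoter_halfwidth,tts_halfwidth Windows as in
#'   [assign_nearest_feature()].
#' @param seed Integer seed.
#' @return A data.frame `category`, `n_obs`, `frac_obs`, `frac_random`,
#'   `fold`. Categories with zero random mass report `fold = Inf` with a
#'   warning.
#' @export
feature_enrichment <- function(peaks, annotation, layout, n_random = 50000L,
                               promoter_halfwidth = 1000L,
                               tts_halfwidth = 1000L, seed = 1L) {
  if (nrow(peaks) == 0L)
    stop_data("no peaks: the observed category distribution is empty")
  n_random <- check_count(n_random, "n_random", min = nrow(peaks))
  set.seed(derive_seed(seed, 87L))

  obs <- assign_nearest_feature(peaks, annotation, promoter_halfwidth,
                                tts_halfwidth)
  widths <- sample(peaks$end - peaks$start, n_random, replace = TRUE)
  ci <- sample.int(nrow(layout), n_random, replace = TRUE,
                   prob = layout$length / sum(layout$length))
  start <- floor(stats::runif(n_random, 0,
                              pmax(layout$length[ci] - widths, 1)))
  rand_peaks <- data.frame(chrom = layout$chrom[ci], start = start,
                           end = start + widths, stringsAsFactors = FALSE)
  rnd <- assign_nearest_feature(rand_peaks, annotation, promoter_halfwidth,
                                tts_halfwidth)
  cats <- sort(unique(c(obs$category, rnd$category)))
  n_obs <- as.vector(table(factor(obs$category, levels = cats)))
  n_rnd <- as.vector(table(factor(rnd$category, levels = cats)))
  frac_obs <- n_obs / nrow(obs)
  frac_rnd <- n_rnd / nrow(rnd)
  fold <- ifelse(frac_rnd == 0, Inf, frac_obs / frac_rnd)
  if (any(is.infinite(fold)))
    warning("categories with zero random mass report fold = Inf",
            call. = FALSE)
  data.frame(category = cats, n_obs = n_obs, frac_obs = frac_obs,
             frac_random = frac_rnd, fold = fold, stringsAsFactors = FALSE)
}

#' Average read occupancy around transcription start sites
#'
#' Bins read positions in `[tss - window/2, tss + window/2)` for every
#' gene, flipping minus-strand genes so that bins run upstream to
#' downstream, and averages across genes. Occupancy is reported per
#' million total reads.
#'
#' @param reads Read positions (data.frame `chrom`, `pos`, or list of
#'   them; pooled).
#' @param annotation Gene annotation (non-empty).
#' @param bin Bin width in bp.
#' @param window Window width in bp (multiple of `bin`).
#' @return A data.frame `offset` (bin start relative to the TSS, oriented)
#'   and `mean_occupancy` (mean reads per gene per bin, per million total
#'   reads).
#' @export
tss_metaprofile <- function(reads, annotation, bin = 50L, window = 2000L) {
  if (nrow(annotation) == 0L)
    stop_data("annotation is empty")
  if (window %% bin != 0L)
    stop_data("window (%d) must be a multiple of bin (%d)", window, bin)
  if (is.data.frame(reads)) reads <- list(reads)
  rd <- do.call(rbind, lapply(reads, function(x) x[c("chrom", "pos")]))
  nb <- window %/% bin
  half <- window %/% 2L
  total_reads <- nrow(rd)
  counts <- numeric(nb)
  if (total_reads > 0L) {
    win <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(annotation$tss - half + 1L, width = window)
    )
    pts <- GenomicRanges::GRanges(rd$chrom,
                                  IRanges::IRanges(rd$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(win, pts)
    g <- S4Vectors::queryHits(hits)
    off <- rd$pos[S4Vectors::subjectHits(hits)] - annotation$tss[g]
    flip <- annotation$strand[g] == "-"
    off[flip] <- -off[flip]
    # oriented offsets in [-half, half); on flipped genes -pos can hit +half
    keep <- off >= -half & off < half
    bidx <- (off[keep] + half) %/% bin + 1L
    counts <- as.vector(table(factor(bidx, levels = seq_len(nb))))
  }
  per_million <- if (total_reads > 0L) total_reads / 1e6 else 1
  data.frame(offset = seq_len(nb) * bin - bin - half,
             mean_occupancy = counts / nrow(annotation) / per_million)
}

#' Fraction of the genome covered by peaks
#'
#' @param peaks Disjoint peak data.frame (merge first).
#' @param layout Genome layout (`chrom`, `length`).
#' @return Total peak width divided by total genome length.
#' @export
genome_coverage_fraction <- function(peaks, layout) {
  if (nrow(peaks) == 0L) return(0)
  gr <- peaks_to_granges(peaks)
  if (length(gr) > 1L && any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    stop_data("peaks must be disjoint; run merge_regions() first")
  sum(peaks$end - peaks$start) / sum(layout$length)
}
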