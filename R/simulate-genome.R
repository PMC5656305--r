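# Synthetic genomes and ChIP peak replicates with known ground truth.
#
# The generators emulate the structure of a two-replicate ChIP experiment
# in fly heads: concordant binding regions with negative-binomial read
# counts, plus two classes of spurious regions (low signal, replicate
# discordance) that the concordance cascade is expected to remove.

#' Generate a synthetic genome layout and gene annotation
#'
#' Places `n_genes` non-overlapping gene bodies (2-8 kb) across
#' `n_chromosomes` chromosomes of equal length, with random strands.
#' TSS/TES follow strand orientation: on the minus strand the TSS is the
#' higher genomic coordinate.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in base pairs.
#' @param n_genes Total number of genes to place.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with class `genome_sim`: `layout` (data.frame `chrom`,
#'   `length`) and `annotation` (data.frame `gene_id`, `chrom`, `strand`,
#'   `tss`, `tes`, 0-based).
#' @export
make_genome <- function(n_chromosomes = 4L, chrom_length = 8e6, n_genes = 2000L,
                        seed = 1L) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 1L)
  check_number(chrom_length, "chrom_length", lower = 1, strict_lower = FALSE)
  n_genes <- check_count(n_genes, "n_genes", min = 0L)
  set.seed(derive_seed(seed, 11L))

  layout <- data.frame(
    chrom = sprintf("chr%d", seq_len(n_chromosomes)),
    length = rep(as.integer(chrom_length), n_chromosomes),
    stringsAsFactors = FALSE
  )
  if (n_genes == 0L) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(), tes = integer(),
                      stringsAsFactors = FALSE)
    return(structure(list(layout = layout, annotation = ann),
                     class = "genome_sim"))
  }

  min_body <- 2000L
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chromosomes + 1L)))
  if (any(per_chrom * min_body > chrom_length))
    stop_data("capacity error: %d gene bodies of >= %d bp cannot fit in a %d bp chromosome",
              max(per_chrom), min_body, as.integer(chrom_length))

  pieces <- vector("list", n_chromosomes)
  gi <- 0L
  for (ci in seq_len(n_chromosomes)) {
    m <- per_chrom[ci]
    if (m == 0L) next
    max_body <- max(min_body, min(8000L, floor(chrom_length / m)))
    len <- sample(seq.int(min_body, max_body), m, replace = TRUE)
    while (sum(len) > chrom_length) # rare when max_body is capacity-capped
      len <- sample(seq.int(min_body, max_body), m, replace = TRUE)
    free <- chrom_length - sum(len)
    starts <- floor(sort(stats::runif(m, 0, free))) +
      cumsum(c(0L, len[-m]))
    ends <- starts + len
    strand <- sample(c("+", "-"), m, replace = TRUE)
    pieces[[ci]] <- data.frame(
      gene_id = sprintf("g%05d", gi + seq_len(m)),
      chrom = layout$chrom[ci],
      strand = strand,
      tss = ifelse(strand == "+", starts, ends - 1L),
      tes = ifelse(strand == "+", ends - 1L, starts),
      stringsAsFactors = FALSE
    )
    gi <- gi + m
  }
  ann <- do.call(rbind, pieces)
  rownames(ann) <- NULL
  structure(list(layout = layout, annotation = ann), class = "genome_sim")
}

#' Simulate two-replicate ChIP peak calls with planted truth
#'
#' Plants four classes of binding regions on a synthetic genome:
#' \describe{
#'   \item{true promoter}{centered within 1 kb of a TSS; NB counts with
#'     mean `mean_depth` in both replicates}
#'   \item{true distal}{same signal, placed away from promoters}
#'   \item{low signal}{NB mean `low_signal_depth` in both replicates}
#'   \item{discordant}{NB mean `mean_depth` in one replicate and
#'     `mean_depth / discordant_ratio` in the other}
#' }
#' Per-replicate peak boundaries are jittered independently so that
#' merging the two call sets is a real operation. Read 5' positions are
#' drawn uniformly within each region, consistent with the counts.
#'
#' By default both replicates are assigned a common library size
#' (depth-matched sequencing); set `equal_library_sizes = FALSE` to use
#' the realised per-replicate read totals instead.
#'
#' @param genome A `genome_sim` object from [make_genome()].
#' @param n_true_promoter,n_true_distal,n_low_signal,n_discordant Number
#'   of regions of each class.
#' @param mean_depth Expected reads per true region per replicate.
#' @param dispersion NB dispersion `d` (variance `mu + d mu^2`).
#' @param low_signal_depth Expected reads of low-signal regions.
#' @param discordant_ratio Expected replicate ratio of discordant regions.
#' @param peak_width Width of planted regions in bp.
#' @param equal_library_sizes Use a common nominal library size.
#' @param seed Integer seed.
#' @return A list with class `peak_sim`: `peaks_rep1`/`peaks_rep2`
#'   (jittered per-replicate intervals with `name` = region id), `regions`
#'   (the planted intervals), `counts` (region x replicate raw counts),
#'   `reads` (list of two data.frames `chrom`, `pos`), `library_sizes`,
#'   and `truth` (`region_id`, `class`, `status`, `reason`).
#' @export
simulate_peak_replicates <- function(genome,
                                     n_true_promoter = 1200L,
                                     n_true_distal = 600L,
                                     n_low_signal = 400L,
                                     n_discordant = 400L,
                                     mean_depth = 500,
                                     dispersion = 0.05,
                                     low_signal_depth = 20,
                                     discordant_ratio = 3,
                                     peak_width = 400L,
                                     equal_library_sizes = TRUE,
                                     seed = 1L) {
  n_true_promoter <- check_count(n_true_promoter, "n_true_promoter")
  n_true_distal <- check_count(n_true_distal, "n_true_distal")
  n_low_signal <- check_count(n_low_signal, "n_low_signal")
  n_discordant <- check_count(n_discordant, "n_discordant")
  check_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_number(mean_depth, "mean_depth", lower = 0, strict_lower = TRUE)
  set.seed(derive_seed(seed, 23L))
  ann <- genome$annotation
  layout <- genome$layout

  n_total <- n_true_promoter + n_true_distal + n_low_signal + n_discordant
  empty_reads <- data.frame(chrom = character(), pos = integer(),
                            stringsAsFactors = FALSE)
  if (n_total == 0L) {
    empty_peaks <- data.frame(chrom = character(), start = integer(),
                              end = integer(), name = character(),
                              stringsAsFactors = FALSE)
    return(structure(list(
      peaks_rep1 = empty_peaks, peaks_rep2 = empty_peaks,
      regions = empty_peaks,
      counts = matrix(integer(), 0, 2, dimnames = list(NULL, c("rep1", "rep2"))),
      reads = list(rep1 = empty_reads, rep2 = empty_reads),
      library_sizes = c(rep1 = 1, rep2 = 1),
      truth = data.frame(region_id = character(), class = character(),
                         status = character(), reason = character(),
                         stringsAsFactors = FALSE)
    ), class = "peak_sim"))
  }
  if (n_true_promoter > 0L && nrow(ann) == 0L)
    stop_data("promoter-class peaks need a non-empty gene annotation")

  half <- floor(peak_width / 2)
  classes <- rep(c("true_promoter", "true_distal", "low_signal", "discordant"),
                 c(n_true_promoter, n_true_distal, n_low_signal, n_discordant))

  # promoter regions: center within +/- 500 bp of a sampled TSS. Only TSSs
  # spaced far enough apart are eligible so promoter regions cannot clash
  # with one another.
  min_gap <- 200L
  tss_spacing <- 2L * (500L + half + min_gap) + 100L
  eligible_tss <- function() {
    keep <- logical(nrow(ann))
    for (ch in unique(ann$chrom)) {
      idx <- which(ann$chrom == ch)
      idx <- idx[order(ann$tss[idx])]
      last <- -Inf
      for (i in idx) {
        if (ann$tss[i] - last >= tss_spacing) {
          keep[i] <- TRUE
          last <- ann$tss[i]
        }
      }
    }
    which(keep)
  }
  elig <- if (n_true_promoter > 0L) eligible_tss() else integer()
  if (n_true_promoter > length(elig))
    stop_data("capacity error: only %d TSSs are spaced widely enough for %d promoter peaks",
              length(elig), n_true_promoter)
  place_promoter <- function(m, pool = elig) {
    idx <- pool[sample.int(length(pool), m)]
    center <- ann$tss[idx] + sample.int(1001L, m, replace = TRUE) - 501L
    len <- layout$length[match(ann$chrom[idx], layout$chrom)]
    center <- pmin(pmax(center, half), len - half)
    data.frame(chrom = ann$chrom[idx], start = center - half,
               end = center + half, stringsAsFactors = FALSE)
  }
  place_uniform <- function(m) {
    ci <- sample.int(nrow(layout), m, replace = TRUE,
                     prob = layout$length / sum(layout$length))
    start <- floor(stats::runif(m, 0, layout$length[ci] - peak_width))
    data.frame(chrom = layout$chrom[ci], start = start,
               end = start + peak_width, stringsAsFactors = FALSE)
  }

  # rejection loop: keep planted regions separated by > 200 bp so jittered
  # replicate calls merge back to one region per planted site. Promoter
  # regions are non-clashing by construction; only uniform placements are
  # redrawn.
  regions <- rbind(
    if (n_true_promoter) place_promoter(n_true_promoter),
    if (n_true_distal) place_uniform(n_true_distal),
    if (n_low_signal) place_uniform(n_low_signal),
    if (n_discordant) place_uniform(n_discordant)
  )
  for (iter in seq_len(100L)) {
    gr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
    wide <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2L * min_gap,
                                  fix = "center")
    hits <- GenomicRanges::countOverlaps(wide, wide)
    clash <- which(hits > 1L)
    redo_unif <- clash[classes[clash] != "true_promoter"]
    if (length(redo_unif) == 0L) break
    regions[redo_unif, ] <- place_uniform(length(redo_unif))
  }
  if (length(clash <- which(GenomicRanges::countOverlaps(
    gr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end)),
    gr) > 1L)) > 0L)
    stop_data("could not place %d regions without overlap; genome too small",
              length(clash))

  regions$name <- sprintf("region_%04d", seq_len(n_total))

  size <- 1 / dispersion
  mu1 <- mu2 <- rep(mean_depth, n_total)
  mu1[classes == "low_signal"] <- low_signal_depth
  mu2[classes == "low_signal"] <- low_signal_depth
  disc <- which(classes == "discordant")
  low_rep <- sample(c(1L, 2L), length(disc), replace = TRUE)
  mu1[disc[low_rep == 1L]] <- mean_depth / discordant_ratio
  mu2[disc[low_rep == 2L]] <- mean_depth / discordant_ratio
  counts <- cbind(rep1 = stats::rnbinom(n_total, mu = mu1, size = size),
                  rep2 = stats::rnbinom(n_total, mu = mu2, size = size))
  rownames(counts) <- regions$name

  reads <- lapply(1:2, function(r) {
    n_reads <- counts[, r]
    ridx <- rep.int(seq_len(n_total), n_reads)
    data.frame(
      chrom = regions$chrom[ridx],
      pos = floor(stats::runif(sum(n_reads), regions$start[ridx],
                               regions$end[ridx])),
      stringsAsFactors = FALSE
    )
  })
  names(reads) <- c("rep1", "rep2")

  jitter_calls <- function() {
    j1 <- sample.int(51L, n_total, replace = TRUE) - 1L
    j2 <- sample.int(51L, n_total, replace = TRUE) - 1L
    data.frame(chrom = regions$chrom,
               start = pmax(regions$start - j1, 0L),
               end = regions$end + j2,
               name = regions$name, stringsAsFactors = FALSE)
  }
  lib <- c(rep1 = sum(counts[, 1L]), rep2 = sum(counts[, 2L]))
  if (equal_library_sizes) lib <- c(rep1 = round(mean(lib)), rep2 = round(mean(lib)))

  truth <- data.frame(
    region_id = regions$name,
    class = classes,
    status = ifelse(classes %in% c("true_promoter", "true_distal"),
                    "true", "spurious"),
    reason = ifelse(classes == "low_signal", "low_signal",
                    ifelse(classes == "discordant", "discordant", "")),
    stringsAsFactors = FALSE
  )
  structure(list(
    peaks_rep1 = jitter_calls(), peaks_rep2 = jitter_calls(),
    regions = regions, counts = counts, reads = reads,
    library_sizes = lib, truth = truth
  ), class = "peak_sim")
}
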