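# Readers and writers for the plain-text formats the pipeline exchanges:
# BED intervals, GTF-like gene annotation tables, TSV count matrices,
# one-id-per-line gene lists and GMT gene-set collections.
#
# All genomic coordinates are 0-based half-open internally (BED native).
# Annotation tables written in 1-based coordinates are converted at the
# reader with an explicit flag.

#' Read a BED file of genomic intervals
#'
#' Parses the first three (plus optional name, score, strand) columns of a
#' BED file into a peak data.frame. Coordinates stay 0-based half-open.
#' `track` and `browser` lines and `#` comments are ignored.
#'
#' @param path Path to a tab-separated BED file.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(vapply(fields, length, 1L))
  if (ncol < 3L)
    stop_data("BED file '%s': fewer than 3 columns", path)
  get <- function(i) vapply(fields, `[[`, "", i)
  out <- data.frame(chrom = get(1L),
                    start = suppressWarnings(as.integer(get(2L))),
                    end = suppressWarnings(as.integer(get(3L))),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1L]
    stop_data("BED file '%s': non-numeric coordinate at data line %d", path, bad)
  }
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1L]
    stop_data("BED file '%s': start >= end at data line %d", path, bad)
  }
  if (ncol >= 4L) out$name <- get(4L)
  if (ncol >= 5L) out$score <- suppressWarnings(as.numeric(get(5L)))
  if (ncol >= 6L) out$strand <- get(6L)
  out
}

#' Write intervals as BED
#'
#' @param peaks A data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optional `name`, `score`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  n <- nrow(peaks)
  cols <- list(peaks$chrom, peaks$start, peaks$end)
  cols <- c(cols, list(
    if (!is.null(peaks$name)) peaks$name else paste0("region_", seq_len(n)),
    if (!is.null(peaks$score)) peaks$score else rep(0, n),
    if (!is.null(peaks$strand)) peaks$strand else rep(".", n)
  ))
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GTF-like gene annotation table
#'
#' Accepts either the package's native TSV layout (`gene_id`, `chrom`,
#' `strand`, `tss`, `tes`) or a 9-column GTF whose attribute field carries
#' `gene_id "..."`; from GTF input, `gene` (or `transcript`) records are
#' used and the TSS/TES are taken from the stranded feature ends.
#'
#' @param path Path to the annotation file.
#' @param one_based Logical; set `TRUE` when the coordinates in a native
#'   TSV are 1-based so they are shifted onto the internal 0-based scale.
#'   GTF input is always 1-based and converted automatically.
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `tes` (0-based positions).
#' @export
read_annotation <- function(path, one_based = FALSE) {
  first <- readLines(path, n = 1L)
  if (grepl("^gene_id\t", first)) {
    ann <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss", "tes")
    if (!all(need %in% names(ann)))
      stop_data("annotation '%s': missing column(s) %s", path,
                paste(setdiff(need, names(ann)), collapse = ", "))
    if (one_based) {
      ann$tss <- ann$tss - 1L
      ann$tes <- ann$tes - 1L
    }
    return(validate_annotation(ann[need]))
  }
  # 9-column GTF
  gtf <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(gtf) < 9L)
    stop_data("annotation '%s': neither native TSV nor 9-column GTF", path)
  gtf <- gtf[gtf[[3L]] %in% c("gene", "transcript"), , drop = FALSE]
  gene_id <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", gtf[[9L]])
  plus <- gtf[[7L]] == "+"
  ann <- data.frame(
    gene_id = gene_id,
    chrom = gtf[[1L]],
    strand = gtf[[7L]],
    tss = ifelse(plus, gtf[[4L]] - 1L, gtf[[5L]] - 1L),
    tes = ifelse(plus, gtf[[5L]] - 1L, gtf[[4L]] - 1L),
    stringsAsFactors = FALSE
  )
  ann <- ann[!duplicated(ann$gene_id), ]
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id))
    stop_data("annotation: duplicated gene_id '%s'",
              ann$gene_id[anyDuplicated(ann$gene_id)])
  if (!all(ann$strand %in% c("+", "-")))
    stop_data("annotation: strand must be '+' or '-'")
  if (any(ann$tss == ann$tes))
    stop_data("annotation: tss == tes for gene '%s'",
              ann$gene_id[ann$tss == ann$tes][1L])
  rownames(ann) <- NULL
  ann
}

#' Write a gene annotation table
#' @param annotation Annotation data.frame (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' The first column holds gene ids, the header row sample ids. Cells must
#' be non-negative integers; fractional values are an error unless
#' `allow_float = TRUE`, which rounds them with a warning.
#'
#' @param path Path to the TSV.
#' @param allow_float Coerce non-integer cells by rounding instead of
#'   raising an error.
#' @return An integer matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_count_matrix <- function(path, allow_float = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stop_data("count matrix '%s': duplicated gene id '%s'", path,
              genes[anyDuplicated(genes)])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0))
    stop_data("count matrix '%s': missing or negative counts", path)
  if (any(m != round(m))) {
    if (!allow_float)
      stop_data("count matrix '%s': non-integer counts (use allow_float to round)", path)
    warning("non-integer counts rounded to integers", call. = FALSE)
    m <- round(m)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV
#' @param counts Integer matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line)
#' @param path Path to the file; blank lines and `#` comments are skipped.
#' @param label Label for the resulting set (defaults to the file name).
#' @return A `gene_set`: list with elements `label` and `members`.
#' @export
read_gene_list <- function(path, label = basename(path)) {
  ids <- readLines(path)
  ids <- trimws(ids[!grepl("^#", ids)])
  gene_set(label, ids[nzchar(ids)])
}

#' Construct a gene set
#' @param label Non-empty label.
#' @param members Character vector of gene ids; duplicates are dropped.
#' @return A list with class `gene_set` and elements `label`, `members`.
#' @export
gene_set <- function(label, members) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop_data("gene set label must be a non-empty string")
  structure(list(label = label, members = unique(as.character(members))),
            class = "gene_set")
}

#' Read a GMT gene-set collection
#'
#' Each line: label, description, then member ids, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return A named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_data("GMT '%s': line with fewer than 3 fields", path)
    gene_set(f[1L], f[-c(1L, 2L)])
  })
  names(sets) <- vapply(sets, `[[`, "", "label")
  sets
}

#' Read courtship observations from a tidy TSV
#' @param path TSV with columns `fly_id`, `genotype`, `condition`, `ci`.
#' @return A validated data.frame.
#' @export
read_courtship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("fly_id", "genotype", "condition", "ci")
  if (!all(need %in% names(tab)))
    stop_data("courtship table '%s': missing column(s) %s", path,
              paste(setdiff(need, names(tab)), collapse = ", "))
  validate_courtship(tab[need])
}

validate_courtship <- function(tab) {
  if (!all(tab$condition %in% c("naive", "trained")))
    stop_data("courtship table: condition must be 'naive' or 'trained'")
  if (any(!nzchar(tab$genotype)))
    stop_data("courtship table: empty genotype")
  if (any(is.na(tab$ci)) || any(tab$ci < 0 | tab$ci > 1))
    stop_data("courtship table: ci must lie in [0, 1]")
  tab
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
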