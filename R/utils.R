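# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_data <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Scalar checks; all thresholds funnel through these so config validation
# and direct calls behave identically.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_data("'%s' must be a single non-missing number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_data("'%s' = %g outside its allowed domain [%s%g, %g%s]",
              name, x, if (strict_lower) "open " else "", lower, upper,
              if (strict_upper) " open" else "")
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, lower = min)
  if (x != as.integer(x))
    stop_data("'%s' must be an integer count", name)
  invisible(as.integer(x))
}

check_proportion <- function(x, name, strict = FALSE) {
  check_number(x, name, lower = 0, upper = 1,
               strict_lower = strict, strict_upper = strict)
}

# Deterministic seed derivation for sub-stages: keeps every generator on its
# own stream while a single user-facing seed controls the whole run.
# Result stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2000L + as.integer(offset) %% 2000L
}

# Peaks live in data.frames (chrom, start, end, ...) with 0-based half-open
# coordinates; conversion to GRanges is centralised here.
peaks_to_granges <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) > 0 && any(peaks$start >= peaks$end))
    stop_data("invalid interval(s): start >= end at row(s) %s",
              paste(utils::head(which(peaks$start >= peaks$end), 5), collapse = ", "))
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

granges_to_peaks <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
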