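#' Peak collection
#'
#' One peak-calling program's set of intervals on a shared genome. All
#' coordinates in this package are 0-based half-open (BED convention):
#' an interval `[start, end)` has length `end - start`. Intervals within a
#' collection may overlap; every derived union statistic (coverage, support)
#' first collapses the collection to its union so overlap is harmless.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `strand`, `score`.
#' @param program label for the program that produced the peaks.
#' @return An object of class `peak_collection`: a list with `program` and a
#'   sorted `intervals` data.frame.
#' @export
peak_collection <- function(intervals, program = "peaks") {
  stopifnot(is.data.frame(intervals))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(intervals))
  if (length(miss)) stop("intervals missing column(s): ", paste(miss, collapse = ", "))
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  if (nrow(intervals)) {
    if (any(!is.finite(intervals$start)) || any(!is.finite(intervals$end)))
      stop("non-numeric interval coordinates")
    bad <- which(intervals$start < 0 | intervals$start >= intervals$end)
    if (length(bad))
      stop("invalid interval (need 0 <= start < end) at row ",
           bad[1], ": ", intervals$chrom[bad[1]], ":",
           intervals$start[bad[1]], "-", intervals$end[bad[1]])
    o <- order(intervals$chrom, intervals$start, intervals$end)
    intervals <- intervals[o, , drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(list(program = as.character(program), intervals = intervals),
            class = "peak_collection")
}

#' @export
print.peak_collection <- function(x, ...) {
  cat("peak_collection '", x$program, "': ", nrow(x$intervals),
      " interval(s)\n", sep = "")
  invisible(x)
}

#' Number of peaks in a collection
#' @param x a `peak_collection`.
#' @export
n_peaks <- function(x) nrow(x$intervals)

# Convert 0-based half-open intervals to a GRanges (1-based closed).
# `genome` (optional) supplies seqlevels/seqlengths so coverage Rles span
# whole chromosomes.
as_granges <- function(x, genome = NULL) {
  df <- if (inherits(x, "peak_collection")) x$intervals else x
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  if (!is.null(genome)) {
    check_chroms(df$chrom, genome)
    gr <- GenomicRanges::GRanges(
      seqnames = factor(df$chrom, levels = genome$chrom_names),
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = if (length(strand) == 1 && nrow(df) > 0) rep(strand, nrow(df)) else strand
    )
    suppressWarnings(GenomeInfoDb::`seqlengths<-`(gr, genome$chrom_lengths))
  } else {
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = if (length(strand) == 1 && nrow(df) > 0) rep(strand, nrow(df)) else strand
    )
  }
}

# Union width in bp of a collection (overlap-safe coverage).
union_bp <- function(x) {
  if (n_peaks(x) == 0) return(0)
  gr <- as_granges(x)
  sum(as.numeric(IRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE))))
}

# Per-chromosome 0/1 coverage RleList of a collection's union over the
# genome's chromosomes (full chromosome lengths, zeros filled).
union_coverage_rle <- function(x, genome) {
  gr <- as_granges(x, genome)
  cov <- GenomicRanges::coverage(GenomicRanges::reduce(gr, ignore.strand = TRUE))
  cov
}
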