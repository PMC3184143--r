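#' Per-caller peak summary statistics
#'
#' Computes, for one program's peak set: peak count, union base-pair
#' coverage, percent genome coverage, and the mean and sample SD of peak
#' bandwidths (bandwidth = `end - start`). Coverage uses the union of the
#' intervals so within-set overlap never double-counts a base pair, while
#' bandwidth statistics are computed over the raw (possibly overlapping)
#' peaks; the two conventions can therefore disagree slightly
#' (`bandwidth_mean` vs `coverage_bp / peak_count`, exposed as
#' `coverage_per_peak`).
#'
#' @param peaks a [peak_collection()].
#' @param genome_size genome size in bp used for percent coverage. Passing
#'   a published assembly constant (e.g. 389e6) reproduces a study's printed
#'   percentages; passing `sum(chrom_lengths)` uses the actual sequence.
#' @return list of class `peak_summary` with fields `program`, `peak_count`,
#'   `coverage_bp`, `percent_coverage`, `bandwidth_mean`, `bandwidth_sd`,
#'   `coverage_per_peak` (bandwidths are `NA` for an empty collection).
#' @export
summarize_peaks <- function(peaks, genome_size) {
  stopifnot(inherits(peaks, "peak_collection"),
            is.numeric(genome_size), genome_size > 0)
  n <- n_peaks(peaks)
  if (n == 0) {
    return(structure(list(program = peaks$program, peak_count = 0L,
                          coverage_bp = 0, percent_coverage = 0,
                          bandwidth_mean = NA_real_, bandwidth_sd = NA_real_,
                          coverage_per_peak = NA_real_),
                     class = "peak_summary"))
  }
  bw <- peaks$intervals$end - peaks$intervals$start
  cov <- union_bp(peaks)
  structure(list(program = peaks$program,
                 peak_count = n,
                 coverage_bp = cov,
                 percent_coverage = 100 * cov / genome_size,
                 bandwidth_mean = mean(bw),
                 bandwidth_sd = if (n > 1) stats::sd(bw) else NA_real_,
                 coverage_per_peak = cov / n),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("peak_summary '%s': %d peaks, %s bp (%.1f%%), bandwidth %.1f +/- %.1f\n",
              x$program, x$peak_count, format(x$coverage_bp, big.mark = ","),
              x$percent_coverage, x$bandwidth_mean, x$bandwidth_sd))
  invisible(x)
}

#' Percent genome coverage, rounded as reported
#'
#' @param coverage_bp union base-pair coverage.
#' @param genome_size genome size in bp.
#' @param digits decimal places in the report (default 1).
#' @return `round(100 * coverage_bp / genome_size, digits)`.
#' @export
percent_coverage <- function(coverage_bp, genome_size, digits = 1) {
  round(100 * coverage_bp / genome_size, digits)
}

#' Coverage per peak, rounded as reported
#'
#' The "coverage / count" bandwidth convention: summed union coverage
#' divided by the number of peaks.
#'
#' @param coverage_bp union base-pair coverage.
#' @param peak_count number of peaks.
#' @param digits decimal places (default 1).
#' @export
coverage_per_peak <- function(coverage_bp, peak_count, digits = 1) {
  round(coverage_bp / peak_count, digits)
}

#' Summary table across callers
#'
#' One row per program with the columns of a standard peak-caller
#' comparison table: count, base-pair coverage, percent coverage (1
#' decimal), mean bandwidth and bandwidth SD (1 decimal).
#'
#' @param collections list of [peak_collection()]s.
#' @param genome_size shared genome size in bp.
#' @return data.frame with columns `program`, `peak_count`, `coverage_bp`,
#'   `percent_coverage`, `bandwidth_mean`, `bandwidth_sd`.
#' @export
metrics_table <- function(collections, genome_size) {
  stopifnot(length(collections) >= 1)
  nm <- vapply(collections, function(x) x$program, "")
  if (anyDuplicated(nm))
    stop("duplicate program names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  rows <- lapply(collections, function(pc) {
    s <- summarize_peaks(pc, genome_size)
    data.frame(program = s$program, peak_count = s$peak_count,
               coverage_bp = s$coverage_bp,
               percent_coverage = round(s$percent_coverage, 1),
               bandwidth_mean = round(s$bandwidth_mean, 1),
               bandwidth_sd = round(s$bandwidth_sd, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
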