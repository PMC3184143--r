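#' Genome specification
#'
#' A named set of chromosome lengths plus the total genome size used for
#' percent-coverage computations. `total_size` defaults to the sum of the
#' chromosome lengths but can be overridden by an explicit constant (e.g. a
#' published assembly size such as 389 Mb for rice) so that percent coverage
#' is computed against the same denominator a study reports.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param total_size optional explicit genome size in bp; defaults to
#'   `sum(chrom_lengths)`.
#' @return An object of class `genome_spec` with fields `chrom_names`,
#'   `chrom_lengths` and `total_size`.
#' @examples
#' genome_spec(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_spec <- function(chrom_lengths, total_size = NULL) {
  if (!is.numeric(chrom_lengths) || length(chrom_lengths) < 1L)
    stop("chrom_lengths must be a non-empty numeric vector")
  nm <- names(chrom_lengths)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every chromosome length must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(chrom_lengths <= 0))
    stop("chromosome lengths must be > 0")
  lens <- stats::setNames(as.numeric(chrom_lengths), nm)
  if (is.null(total_size)) total_size <- sum(lens)
  if (total_size <= 0) stop("total_size must be > 0")
  structure(
    list(chrom_names = nm, chrom_lengths = lens, total_size = total_size),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp",
      "(total_size", format(x$total_size, big.mark = ","), "bp)\n")
  invisible(x)
}

# Check that chromosome names used by an object all exist in the genome;
# silent renaming (e.g. "chr" prefixes) is deliberately not attempted.
check_chroms <- function(chroms, genome, what = "intervals") {
  bad <- setdiff(unique(chroms), genome$chrom_names)
  if (length(bad))
    stop("chromosome name(s) in ", what,
         " not present in genome: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
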