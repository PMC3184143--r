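#' Log-transform expression and compute z-scores
#'
#' Each raw expression value x_g is log10-transformed and standardized:
#' z_g = (log10(x_g) - mu) / sigma, where mu and sigma are the mean and
#' sample SD (n - 1 denominator) of the log10 values across genes. The
#' resulting z-scores have mean 0 and SD 1 by construction.
#'
#' @param values named numeric vector of strictly positive raw expression
#'   values (one per gene), e.g. from [read_expression_table()].
#' @return data.frame of class `expression_table` with columns `gene_id`,
#'   `raw`, `log10`, `z`, and attributes `mu` and `sigma`.
#' @export
compute_zscores <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("expression values must be named by gene id")
  if (anyDuplicated(names(values)))
    stop("duplicate gene ids in expression values")
  if (length(values) < 2) stop("need at least 2 genes to standardize")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("expression values must be finite and > 0 (log10 transform)")
  lg <- log10(values)
  mu <- mean(lg)
  sigma <- stats::sd(lg)
  if (sigma == 0) stop("zero variance in log10 expression; z-scores undefined")
  out <- data.frame(gene_id = names(values), raw = as.numeric(values),
                    log10 = as.numeric(lg), z = as.numeric((lg - mu) / sigma),
                    stringsAsFactors = FALSE)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Discretize z-scored expression into high / middle / low
#'
#' `high` iff z >= `hi_cut`; `low` iff z <= `lo_cut`; `middle` otherwise.
#' The default cuts of +/- 0.5 SD are a conventional three-way split and
#' are fully configurable.
#'
#' @param table an `expression_table` from [compute_zscores()].
#' @param hi_cut,lo_cut z-score cutoffs with `lo_cut < hi_cut`.
#' @return the table with an added `category` column and attributes
#'   `counts` and `percents` (per category, categories ordered
#'   high/middle/low).
#' @export
discretize_expression <- function(table, hi_cut = 0.5, lo_cut = -0.5) {
  stopifnot(inherits(table, "expression_table"))
  if (!(lo_cut < hi_cut)) stop("need lo_cut < hi_cut")
  cat_ <- ifelse(table$z >= hi_cut, "high",
                 ifelse(table$z <= lo_cut, "low", "middle"))
  table$category <- cat_
  lv <- c("high", "middle", "low")
  counts <- base::table(factor(cat_, levels = lv))
  attr(table, "counts") <- stats::setNames(as.integer(counts), lv)
  attr(table, "percents") <- stats::setNames(
    100 * as.integer(counts) / nrow(table), lv)
  table
}

#' Category shares from counts, as whole percents summing to 100
#'
#' Percent of the gene universe in each category, rounded to whole
#' percents with the largest-remainder method so the reported shares sum
#' to exactly 100 (the convention behind published three-way splits such
#' as 33/28/39).
#'
#' @param counts named integer vector of category counts.
#' @return named numeric vector of whole percents summing to 100.
#' @export
category_percents <- function(counts) {
  pct <- 100 * counts / sum(counts)
  fl <- floor(pct)
  short <- 100 - sum(fl)
  if (short > 0) {
    give <- order(pct - fl, decreasing = TRUE)[seq_len(short)]
    fl[give] <- fl[give] + 1
  }
  fl
}
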