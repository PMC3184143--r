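## Association between expression category and peak position label:
## 3 x 4 contingency table, conditional probabilities P(expr | label), and
## one-sided hypergeometric over-representation tests per cell. The
## complementary-cell p-values of ~1.0 seen in such grids are the signature
## of a one-sided test, which is the default here.

EXPR_LEVELS <- c("high", "middle", "low")
LABEL_LEVELS <- c("within", "upstream", "downstream", "none")

#' Cross-classify genes by expression category and peak label
#'
#' Builds the 3 x 4 table of gene counts (expression high/middle/low by
#' label within/upstream/downstream/none). Genes present in only one of
#' the two inputs are excluded (their number is reported via a message),
#' mirroring analyses restricted to genes with expression values.
#'
#' @param labels data.frame with columns `gene_id`, `label` (one row per
#'   gene), e.g. from [classify_genes()].
#' @param categories data.frame with columns `gene_id`, `category`, e.g. a
#'   discretized expression table.
#' @return integer matrix with rows `high/middle/low` and columns
#'   `within/upstream/downstream/none`.
#' @export
build_contingency <- function(labels, categories) {
  stopifnot(all(c("gene_id", "label") %in% names(labels)),
            all(c("gene_id", "category") %in% names(categories)))
  if (anyDuplicated(labels$gene_id))
    stop("duplicate gene entries in labels")
  if (anyDuplicated(categories$gene_id))
    stop("duplicate gene entries in categories")
  if (any(!labels$label %in% LABEL_LEVELS))
    stop("unknown label value(s): ",
         paste(setdiff(labels$label, LABEL_LEVELS), collapse = ", "))
  if (any(!categories$category %in% EXPR_LEVELS))
    stop("unknown category value(s): ",
         paste(setdiff(categories$category, EXPR_LEVELS), collapse = ", "))
  m <- merge(labels[, c("gene_id", "label")],
             categories[, c("gene_id", "category")], by = "gene_id")
  dropped <- nrow(labels) + nrow(categories) - 2 * nrow(m)
  if (dropped > 0)
    message(dropped, " gene(s) present in only one input were excluded")
  if (nrow(m) == 0) stop("no genes shared between labels and categories")
  tab <- base::table(factor(m$category, levels = EXPR_LEVELS),
                     factor(m$label, levels = LABEL_LEVELS))
  mat <- matrix(as.integer(tab), nrow = 3,
                dimnames = list(EXPR_LEVELS, LABEL_LEVELS))
  mat
}

#' Conditional probabilities P(expression | label)
#'
#' Each cell divided by its label-column marginal, so each column sums
#' to 1. Columns with a zero marginal are reported as `NA` (absent, not an
#' error).
#'
#' @param tab contingency matrix from [build_contingency()].
#' @return numeric matrix of the same shape.
#' @export
conditional_probabilities <- function(tab) {
  cs <- colSums(tab)
  out <- sweep(tab, 2, cs, "/")
  out[, cs == 0] <- NA_real_
  out
}

#' Hypergeometric over-representation test for one cell
#'
#' Tests whether the count in cell (expr, label) is larger than expected
#' if expression category and peak label were independent: the upper-tail
#' probability P(X >= k) with X ~ Hypergeometric(N = grand total,
#' K = expression-row marginal, n = label-column marginal), k = cell
#' count. The parameterization is symmetric: swapping which marginal plays
#' "successes" versus "draws" gives the same p-value.
#'
#' @param tab contingency matrix from [build_contingency()].
#' @param expr one of `"high"`, `"middle"`, `"low"`.
#' @param label one of `"within"`, `"upstream"`, `"downstream"`, `"none"`.
#' @param alternative `"greater"` (over-representation, default) or
#'   `"less"`.
#' @return p-value in \[0, 1\].
#' @export
hypergeometric_cell_test <- function(tab, expr, label,
                                     alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  expr <- match.arg(expr, EXPR_LEVELS)
  label <- match.arg(label, LABEL_LEVELS)
  k <- tab[expr, label]
  K <- sum(tab[expr, ])
  n <- sum(tab[, label])
  N <- sum(tab)
  if (n > N || K > N) stop("marginals exceed grand total")
  if (alternative == "greater")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
}

#' Significance grid over all expression-by-label cells
#'
#' Tests every cell of the contingency table for over-representation and
#' flags cells at the cutoff (default 1e-2, a conventional raw-p cutoff
#' for such grids). No multiple-testing correction is applied by default;
#' `adjust = "BY"` applies a Benjamini-Yekutieli adjustment across the 12
#' cells before flagging.
#'
#' @param tab contingency matrix from [build_contingency()].
#' @param alpha significance cutoff.
#' @param adjust `"none"` (default) or `"BY"`.
#' @return data.frame with columns `expression`, `label`, `p`,
#'   (`p_adj` when adjusted) and `significant`.
#' @export
significance_report <- function(tab, alpha = 1e-2, adjust = c("none", "BY")) {
  adjust <- match.arg(adjust)
  grid <- expand.grid(expression = EXPR_LEVELS, label = LABEL_LEVELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$p <- mapply(function(e, l) hypergeometric_cell_test(tab, e, l),
                   grid$expression, grid$label)
  if (adjust == "BY") {
    grid$p_adj <- stats::p.adjust(grid$p, method = "BY")
    grid$significant <- grid$p_adj < alpha
  } else {
    grid$significant <- grid$p < alpha
  }
  grid
}

#' Binomial test of genic-read enrichment
#'
#' Upper-tail binomial test that `k_genic` of `n_total` reads falling in
#' genic regions exceeds the expected genic fraction `p0`:
#' p = P(X >= k), X ~ Binomial(n, p0). `p0` would typically be the genic
#' fraction observed in the Input (control) library, so the test contrasts
#' ChIP against control.
#'
#' @param k_genic reads mapped to genic regions.
#' @param n_total total mapped reads.
#' @param p0 expected genic fraction, 0 < p0 < 1.
#' @return p-value.
#' @export
binomial_genic_test <- function(k_genic, n_total, p0) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (k_genic < 0 || k_genic > n_total) stop("need 0 <= k_genic <= n_total")
  stats::pbinom(k_genic - 1, n_total, p0, lower.tail = FALSE)
}
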