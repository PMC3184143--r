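#' Hypergeometric term enrichment with Benjamini-Yekutieli adjustment
#'
#' Tests each annotation term for over-representation in a query gene list
#' against a background of annotated genes. Per term: k = query genes with
#' the term, n = annotated query size, K = background genes with the term,
#' N = annotated background size; raw p is the upper hypergeometric tail
#' P(X >= k). Adjusted p-values use the Benjamini-Yekutieli procedure,
#' p_(i) * m * H(m) / i with H(m) the m-th harmonic number, monotonized
#' step-up and capped at 1 — valid under arbitrary dependence among terms,
#' which overlapping gene sets violate freely.
#'
#' The background universe defaults to all genes with at least one term
#' ("any annotation"); pass `background` to restrict it (e.g. to a
#' genome-wide gene model list — genes without terms are still dropped).
#' Query genes without any annotation are dropped (count reported via a
#' message). If a `parent_map` (child term -> parent term) is supplied,
#' annotations are propagated to all ancestor terms first, as
#' ontology-aware tools do.
#'
#' @param query_genes character vector of query gene ids.
#' @param annotation data.frame with columns `gene_id`, `term_id` and
#'   optionally `description`.
#' @param background optional character vector restricting the universe.
#' @param min_term_size drop terms annotating fewer than this many
#'   background genes (default 2; singleton terms give degenerate tests).
#' @param parent_map optional data.frame with columns `child`, `parent`.
#' @return data.frame with one row per tested term: `term`, `description`,
#'   `k`, `n`, `K`, `N`, `p`, `p_adj`, sorted by `p_adj` then `p`.
#' @export
enrich <- function(query_genes, annotation, background = NULL,
                   min_term_size = 2, parent_map = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  ann <- unique(annotation[, c("gene_id", "term_id")])
  if (!is.null(parent_map)) ann <- propagate_terms(ann, parent_map)
  if (!is.null(background)) ann <- ann[ann$gene_id %in% background, ]
  universe <- unique(ann$gene_id)
  N <- length(universe)
  if (N == 0) stop("empty annotated background")
  query <- unique(query_genes)
  dropped <- sum(!query %in% universe)
  if (dropped > 0)
    message(dropped, " query gene(s) without annotation were dropped")
  query <- query[query %in% universe]
  n <- length(query)
  if (n == 0) stop("empty query after dropping unannotated genes")
  Ktab <- base::table(ann$term_id)
  in_query <- ann[ann$gene_id %in% query, ]
  ktab <- base::table(factor(in_query$term_id, levels = names(Ktab)))
  K <- as.integer(Ktab)
  k <- as.integer(ktab)
  terms <- names(Ktab)
  keep <- K >= min_term_size
  terms <- terms[keep]; K <- K[keep]; k <- k[keep]
  if (!length(terms)) stop("no terms pass min_term_size = ", min_term_size)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BY")
  desc <- rep(NA_character_, length(terms))
  if ("description" %in% names(annotation)) {
    dmap <- unique(annotation[, c("term_id", "description")])
    desc <- dmap$description[match(terms, dmap$term_id)]
  }
  out <- data.frame(term = terms, description = desc, k = k, n = n,
                    K = K, N = N, p = p, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ancestor closure: each gene annotated to a term is also annotated to all
# of the term's ancestors in the parent map
propagate_terms <- function(ann, parent_map) {
  stopifnot(all(c("child", "parent") %in% names(parent_map)))
  repeat {
    m <- merge(ann, parent_map, by.x = "term_id", by.y = "child")
    if (!nrow(m)) break
    extra <- unique(data.frame(gene_id = m$gene_id, term_id = m$parent,
                               stringsAsFactors = FALSE))
    before <- nrow(ann)
    ann <- unique(rbind(ann, extra))
    if (nrow(ann) == before) break
  }
  ann
}

#' Flag and write an enrichment table
#'
#' @param rows output of [enrich()].
#' @param alpha adjusted-p cutoff for the `flag` column.
#' @param path optional TSV output path.
#' @return `rows` with an added logical `flag` column (sorted by `p_adj`).
#' @export
enrichment_report <- function(rows, alpha = 0.05, path = NULL) {
  rows$flag <- rows$p_adj < alpha
  if (!is.null(path)) write_tsv(rows, path)
  rows
}
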