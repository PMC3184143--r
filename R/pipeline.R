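#' Run the full comparative analysis on a simulated study
#'
#' Executes every stage on one synthetic study: peak summary statistics,
#' base-pair consensus support, per-program mean peak height (when pileups
#' were simulated), peak-to-gene classification per caller, expression
#' z-scoring and discretization, the expression-by-label association grid
#' per caller, and (optionally) evaluation of each caller against the
#' planted truth collapsed to enriched/unenriched. Reports are written as
#' TSVs plus a JSON summary when `out_dir` is given; all randomness is
#' fixed by `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional report directory.
#' @param cfg a [classify_config()].
#' @param hi_cut,lo_cut z-score cuts for [discretize_expression()].
#' @param alpha significance cutoff for the association grid.
#' @param tracks simulate pileups (slower) and report peak heights.
#' @return list with `study`, `metrics`, `support`, `heights` (or `NULL`),
#'   `labels` (per program), `expression`, `association` (per program),
#'   `truth_eval`.
#' @export
run_study_pipeline <- function(config = sim_config(), out_dir = NULL,
                               cfg = classify_config(),
                               hi_cut = 0.5, lo_cut = -0.5,
                               alpha = 0.01, tracks = TRUE) {
  study <- simulate_study(config, tracks = tracks)
  gsize <- sum(study$genome$chrom_lengths)
  metrics <- metrics_table(study$callers, gsize)
  support <- support_table(study$callers, study$genome)
  heights <- if (tracks) height_table(study$callers, study$chip) else NULL

  expr <- discretize_expression(compute_zscores(study$expression),
                                hi_cut = hi_cut, lo_cut = lo_cut)
  categories <- data.frame(gene_id = expr$gene_id, category = expr$category,
                           stringsAsFactors = FALSE)

  labels <- lapply(study$callers, function(pc)
    classify_genes(study$genes, pc, cfg))
  association <- lapply(labels, function(lb) {
    tab <- build_contingency(lb, categories)
    list(table = tab,
         conditional = conditional_probabilities(tab),
         report = significance_report(tab, alpha = alpha))
  })

  truth_pred <- do.call(rbind, lapply(names(labels), function(nm)
    data.frame(gene_id = labels[[nm]]$gene_id, program = nm,
               call = collapse_label(labels[[nm]]$label),
               stringsAsFactors = FALSE)))
  gold <- data.frame(gene_id = study$truth$gene_labels$gene_id,
                     result = collapse_label(study$truth$gene_labels$label),
                     stringsAsFactors = FALSE)
  truth_eval <- evaluate_predictions(truth_pred, gold)

  res <- list(study = study, metrics = metrics, support = support,
              heights = heights, labels = labels, expression = expr,
              association = association, truth_eval = truth_eval)
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir, alpha)
  res
}

write_pipeline_reports <- function(res, out_dir, alpha) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$metrics, file.path(out_dir, "peak_metrics.tsv"))
  write_tsv(res$support, file.path(out_dir, "support_profiles.tsv"))
  if (!is.null(res$heights))
    write_tsv(res$heights, file.path(out_dir, "peak_heights.tsv"))
  assoc <- do.call(rbind, lapply(names(res$association), function(nm) {
    rp <- res$association[[nm]]$report
    cbind(program = nm, rp, stringsAsFactors = FALSE)
  }))
  write_tsv(assoc, file.path(out_dir, "association_pvalues.tsv"))
  write_tsv(res$truth_eval, file.path(out_dir, "truth_evaluation.tsv"))
  counts <- attr(res$expression, "counts")
  summary <- list(
    n_genes = nrow(res$expression),
    expression_counts = as.list(counts),
    alpha = alpha,
    significant_cells = lapply(res$association, function(a)
      sum(a$report$significant))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
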