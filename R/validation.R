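#' Collapse a positional label to enriched / unenriched
#'
#' Gold-standard PCR validation reports a single enriched (`+`) or
#' unenriched (`-`) call per gene, so positional labels collapse:
#' within/upstream/downstream -> `+`, none -> `-`.
#'
#' @param label character vector of labels.
#' @return character vector of `"+"` / `"-"`.
#' @export
collapse_label <- function(label) {
  if (any(!label %in% c("within", "upstream", "downstream", "none")))
    stop("unknown label value(s): ",
         paste(setdiff(label, c("within", "upstream", "downstream", "none")),
               collapse = ", "))
  ifelse(label == "none", "-", "+")
}

#' Read a gold-standard enriched/unenriched gene list
#'
#' TSV with columns `gene_id` and `result` (`+` or `-`), header optional.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `result`.
#' @export
read_gold_standard <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("gene_id", "result") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, colClasses = "character")
    names(df)[1:2] <- c("gene_id", "result")
  }
  df <- df[, c("gene_id", "result")]
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s) in gold standard")
  if (any(!df$result %in% c("+", "-")))
    stop("gold-standard results must be '+' or '-'")
  df
}

#' Evaluate program calls against a gold standard
#'
#' Tallies per-program confusion counts (tp, fn, fp, tn) of collapsed
#' enriched/unenriched calls against the gold standard, plus sensitivity
#' tp/(tp+fn) and specificity tn/(tn+fp).
#'
#' @param predictions data.frame with columns `gene_id`, `program`, and
#'   either `call` (`+`/`-`) or `label` (positional, collapsed via
#'   [collapse_label()]).
#' @param gold data.frame with columns `gene_id`, `result` (`+`/`-`).
#' @return data.frame with one row per program: `program`, `tp`, `fn`,
#'   `fp`, `tn`, `sensitivity`, `specificity`.
#' @export
evaluate_predictions <- function(predictions, gold) {
  stopifnot(all(c("gene_id", "program") %in% names(predictions)))
  if (!"call" %in% names(predictions)) {
    if (!"label" %in% names(predictions))
      stop("predictions need a 'call' or 'label' column")
    predictions$call <- collapse_label(predictions$label)
  }
  if (any(!predictions$call %in% c("+", "-")))
    stop("prediction calls must be '+' or '-'")
  programs <- sort(unique(predictions$program))
  rows <- lapply(programs, function(pg) {
    pp <- predictions[predictions$program == pg, ]
    missing <- setdiff(gold$gene_id, pp$gene_id)
    if (length(missing))
      stop("gold-standard gene(s) without a prediction for ", pg, ": ",
           paste(missing, collapse = ", "))
    call <- pp$call[match(gold$gene_id, pp$gene_id)]
    tp <- sum(gold$result == "+" & call == "+")
    fn <- sum(gold$result == "+" & call == "-")
    fp <- sum(gold$result == "-" & call == "+")
    tn <- sum(gold$result == "-" & call == "-")
    data.frame(program = pg, tp = tp, fn = fn, fp = fp, tn = tn,
               sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged ChIP-PCR validation table
#'
#' The gold-standard ChIP-PCR experiment shipped with the package: 23 rice
#' genes (18 PCR-enriched, 5 unenriched) with the enriched/unenriched call
#' each of four peak-calling programs made for them.
#'
#' @return list with `gold` (data.frame `gene_id`, `result`) and
#'   `predictions` (long data.frame `gene_id`, `program`, `call`).
#' @export
chip_pcr_table <- function() {
  path <- system.file("extdata", "chip_pcr_table.tsv",
                      package = "peakcompare", mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = "character")
  gold <- data.frame(gene_id = df$gene_id, result = df$pcr_result,
                     stringsAsFactors = FALSE)
  programs <- setdiff(names(df), c("gene_id", "pcr_result"))
  predictions <- do.call(rbind, lapply(programs, function(pg)
    data.frame(gene_id = df$gene_id, program = pg, call = df[[pg]],
               stringsAsFactors = FALSE)))
  list(gold = gold, predictions = predictions)
}
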