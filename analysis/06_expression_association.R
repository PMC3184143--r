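#!/usr/bin/env Rscript
## Stage 6: discretize expression into high/middle/low by z-score and test
## every (expression category, peak label) cell for over-representation
## with a one-sided hypergeometric test, per caller. The planted repression
## shows up as significant (low | upstream), (low | within) and
## (low | downstream) cells for every caller despite their very different
## peak sets.

source(file.path("analysis", "00_common.R"))

st <- load_study()
expr <- discretize_expression(compute_zscores(st$expression),
                              hi_cut = 0.5, lo_cut = -0.5)
counts <- attr(expr, "counts")
cat("expression categories:",
    paste(names(counts), counts, sep = "=", collapse = ", "),
    "(", paste(category_percents(counts), collapse = "/"), "% )\n")
categories <- data.frame(gene_id = expr$gene_id, category = expr$category)

grid_rows <- list()
cond_rows <- list()
for (nm in names(st$callers)) {
  lb <- classify_genes(st$genes, st$callers[[nm]])
  tab <- build_contingency(lb, categories)
  rep_ <- significance_report(tab, alpha = 0.01)
  rep_$program <- nm
  grid_rows[[nm]] <- rep_
  cp <- conditional_probabilities(tab)
  cond_rows[[nm]] <- data.frame(program = nm,
                                expression = rownames(cp)[row(cp)],
                                label = colnames(cp)[col(cp)],
                                probability = round(as.numeric(cp), 4))
  cat(sprintf("%-10s P(low|upstream)=%.2f P(low|none)=%.2f  p(low,upstream)=%.2e\n",
              nm, cp["low", "upstream"], cp["low", "none"],
              rep_$p[rep_$expression == "low" & rep_$label == "upstream"]))
}
grid <- do.call(rbind, grid_rows)
grid$p <- signif(grid$p, 3)
save_tsv(grid[, c("program", "expression", "label", "p", "significant")],
         "association_pvalues.tsv")
save_tsv(do.call(rbind, cond_rows), "conditional_probabilities.tsv")

## expression table itself
out <- expr
out$log10 <- round(out$log10, 4); out$z <- round(out$z, 4)
save_tsv(out, "expression_categories.tsv")
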