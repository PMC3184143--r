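#!/usr/bin/env Rscript
## Stage 8: evaluate caller gene classifications against gold standards.
## (a) The packaged ChIP-PCR table: 23 genes with wet-lab enriched/
##     unenriched outcomes and each real program's call.
## (b) The synthetic study: each virtual caller's collapsed calls against
##     the planted truth labels.

source(file.path("analysis", "00_common.R"))

## (a) packaged wet-lab gold standard
fx <- chip_pcr_table()
ev <- evaluate_predictions(fx$predictions, fx$gold)
ev$sensitivity <- round(ev$sensitivity, 3)
ev$specificity <- round(ev$specificity, 3)
cat("ChIP-PCR gold standard (18 enriched / 5 unenriched genes):\n")
print(ev)
save_tsv(ev, "chip_pcr_evaluation.tsv")

## (b) synthetic truth
st <- load_study()
gold <- data.frame(gene_id = st$truth$gene_labels$gene_id,
                   result = collapse_label(st$truth$gene_labels$label))
pred <- do.call(rbind, lapply(names(st$callers), function(nm) {
  lb <- classify_genes(st$genes, st$callers[[nm]])
  data.frame(gene_id = lb$gene_id, program = nm,
             call = collapse_label(lb$label))
}))
ev2 <- evaluate_predictions(pred, gold)
ev2$sensitivity <- round(ev2$sensitivity, 3)
ev2$specificity <- round(ev2$specificity, 3)
cat("\nvirtual callers vs planted truth:\n")
print(ev2)
save_tsv(ev2, "truth_evaluation.tsv")
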