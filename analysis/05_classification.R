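#!/usr/bin/env Rscript
## Stage 5: assign every gene one label per caller (within / upstream /
## downstream / none, precedence in that order, 2 kb strand-aware windows)
## and report the label distributions.

source(file.path("analysis", "00_common.R"))

st <- load_study()
cfg <- classify_config(upstream_window = 2000, downstream_window = 2000)

labels <- list()
dist_rows <- list()
for (nm in names(st$callers)) {
  res <- classify_all(st$genes, st$callers[[nm]], cfg)
  labels[[nm]] <- res$labels
  d <- res$distribution
  d$program <- nm
  dist_rows[[nm]] <- d
  cat(sprintf("%-10s multi-category genes before precedence: %d\n",
              nm, attr(res$labels, "multi_label")))
}
dist <- do.call(rbind, dist_rows)
dist$percent <- round(dist$percent, 1)
print(dist[, c("program", "label", "count", "percent")])

save_tsv(do.call(rbind, labels), "gene_labels.tsv")
save_tsv(dist[, c("program", "label", "count", "percent")],
         "label_distribution.tsv")
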