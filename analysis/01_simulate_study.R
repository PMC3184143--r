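#!/usr/bin/env Rscript
## Stage 1: simulate the synthetic study (genome, genes, expression, true
## repressive domains, ChIP/Input pileups, four virtual-caller peak sets)
## and cache the bundle under scratch/study/.

source(file.path("analysis", "00_common.R"))

unlink(STUDY_DIR, recursive = TRUE)
st <- load_study()

cat("genome:", format(sum(st$genome$chrom_lengths), big.mark = ","),
    "bp on", length(st$genome$chrom_names), "chromosomes\n")
cat("genes:", nrow(st$genes), "| marked with a true domain:",
    sum(st$truth$gene_labels$label != "none"), "\n")
print(table(st$truth$gene_labels$label))
cat("virtual callers:", paste(names(st$callers), collapse = ", "), "\n")
cat("study bundle written to", STUDY_DIR, "\n")
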