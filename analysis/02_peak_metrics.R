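#!/usr/bin/env Rscript
## Stage 2: per-caller peak statistics (count, union coverage, percent of
## genome, bandwidth mean/SD), the comparison every caller benchmark opens
## with. The broad caller covers several times more of the genome than the
## sharp one despite calling the same underlying domains.

source(file.path("analysis", "00_common.R"))

st <- load_study()
tab <- metrics_table(st$callers, sum(st$genome$chrom_lengths))
## truth row for reference
truth <- summarize_peaks(st$truth$true_domains, sum(st$genome$chrom_lengths))
tab <- rbind(tab, data.frame(
  program = "truth", peak_count = truth$peak_count,
  coverage_bp = truth$coverage_bp,
  percent_coverage = round(truth$percent_coverage, 1),
  bandwidth_mean = round(truth$bandwidth_mean, 1),
  bandwidth_sd = round(truth$bandwidth_sd, 1)))

print(tab)
save_tsv(tab, "peak_metrics.tsv")
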