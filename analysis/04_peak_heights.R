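#!/usr/bin/env Rscript
## Stage 4: normalize Input to the ChIP total and report per-caller mean
## peak height (max - min ChIP depth inside each peak). Callers whose peaks
## sit on genuine enrichment show higher mean heights than callers whose
## peak sets are diluted by false positives.

source(file.path("analysis", "00_common.R"))

st <- load_study()
nt <- normalize_tracks(st$chip, st$input)
cat(sprintf("normalized input total %.0f == chip total %.0f\n",
            nt$input$total, nt$chip$total))

tab <- height_table(st$callers, st$chip)
print(tab)
save_tsv(tab, "peak_heights.tsv")
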