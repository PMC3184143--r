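#!/usr/bin/env Rscript
## Stage 3: base-pair consensus support. For each caller, what fraction of
## its peak base pairs is also called by 1, 2, 3 or 4 of the callers?
## Permissive callers show a large one-support (unsupported) fraction;
## conservative callers are almost fully corroborated.

source(file.path("analysis", "00_common.R"))

st <- load_study()
tab <- support_table(st$callers, st$genome)
print(tab)
save_tsv(tab, "support_profiles.tsv")
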