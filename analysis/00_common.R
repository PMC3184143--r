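## Shared setup for the numbered analysis scripts: one seeded synthetic
## study at the default conditions, cached under scratch/ so later scripts
## reuse the exact same bundle.

library(peakcompare)

STUDY_SEED <- 20110930L
STUDY_DIR <- file.path("scratch", "study")
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

save_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("wrote", path, "\n")
  invisible(path)
}

load_study <- function(tracks = TRUE) {
  if (dir.exists(STUDY_DIR) && file.exists(file.path(STUDY_DIR, "config.yaml")))
    return(read_study(STUDY_DIR))
  st <- simulate_study(sim_config(seed = STUDY_SEED), tracks = tracks)
  write_study(st, STUDY_DIR, force = TRUE)
  st
}
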