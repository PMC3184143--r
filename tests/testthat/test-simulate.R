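small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, chrom_lengths = c(chrA = 1.5e6, chrB = 1e6),
             n_genes = 150, ...)
}

identity_profile <- function() {
  list(caller_profile("identity", sensitivity = 1, fp_per_mb = 0,
                      jitter_sd = 0, merge_gap = 0))
}

test_that("an identity virtual caller reproduces the true domains exactly", {
  st <- simulate_study(small_cfg(seed = 7, caller_profiles = identity_profile()),
                       tracks = FALSE)
  expect_identical(
    st$callers$identity$intervals[, c("chrom", "start", "end")],
    st$truth$true_domains$intervals[, c("chrom", "start", "end")])
})

test_that("mark_fraction = 0 yields no domains and all-none labels", {
  st <- simulate_study(small_cfg(seed = 2, mark_fraction = 0), tracks = FALSE)
  expect_equal(n_peaks(st$truth$true_domains), 0)
  expect_true(all(st$truth$gene_labels$label == "none"))
})

test_that("simulation is deterministic in the seed and writes byte-identical bundles", {
  cfg <- small_cfg(seed = 42)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$genes, st2$genes)
  expect_identical(st1$expression, st2$expression)
  expect_identical(st1$chip$steps, st2$chip$steps)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(st1, d1, force = TRUE)
  write_study(st2, d2, force = TRUE)
  for (f in dir(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  ## dropping tracks leaves genes/domains/expression/callers untouched
  st3 <- simulate_study(cfg, tracks = FALSE)
  expect_identical(st3$genes, st1$genes)
  expect_identical(st3$callers$sharp$intervals, st1$callers$sharp$intervals)
})

test_that("a written bundle reads back equal to the in-memory study", {
  st <- simulate_study(small_cfg(seed = 5))
  d <- withr::local_tempdir()
  write_study(st, d, force = TRUE)
  expect_equal(length(dir(d, pattern = "\\.bed$")), 5) # 4 callers + truth
  back <- read_study(d)
  expect_identical(back$genes, st$genes)
  expect_identical(back$truth$gene_labels, st$truth$gene_labels)
  expect_identical(back$truth$true_domains$intervals[, c("chrom", "start", "end")],
                   st$truth$true_domains$intervals[, c("chrom", "start", "end")])
  expect_identical(back$chip$steps, st$chip$steps)
  expect_equal(back$expression, st$expression, tolerance = 1e-12)
  ## refuses to clobber without force
  expect_error(write_study(st, d), "non-empty")
})

test_that("genomes too small for the requested gene count are rejected", {
  expect_error(
    simulate_study(sim_config(seed = 1, chrom_lengths = c(chr1 = 1e5),
                              n_genes = 500), tracks = FALSE),
    "too small")
})

test_that("domain placement is consistent with the planted labels", {
  st <- simulate_study(small_cfg(seed = 9, caller_profiles = identity_profile()),
                       tracks = FALSE)
  lb <- classify_genes(st$genes, st$truth$true_domains)
  expect_identical(lb$label, st$truth$gene_labels$label)
})

test_that("pileups are enriched over domains and flat elsewhere", {
  cfg <- small_cfg(seed = 3)
  st <- simulate_study(cfg)
  dom <- st$truth$true_domains$intervals
  hr <- mean_peak_height(st$truth$true_domains, st$chip)
  ## enriched bins have lambda = 16, background 2: domain max depth must
  ## clearly exceed the background mean
  expect_gt(hr$mean_height, 5)
  ## input has no enrichment structure: mean depth near background
  mean_in <- st$input$signal / sum(cfg$chrom_lengths)
  expect_equal(mean_in, cfg$background_depth, tolerance = 0.05)
})

test_that("increasing merge_gap never increases peak count nor decreases mean bandwidth", {
  for (seed in 1:5) {
    prev_count <- Inf; prev_bw <- 0
    for (gap in c(0, 500, 2000, 8000)) {
      cfg <- small_cfg(seed = seed, caller_profiles = list(
        caller_profile("c", sensitivity = 0.9, fp_per_mb = 2,
                       jitter_sd = 100, merge_gap = gap)))
      st <- simulate_study(cfg, tracks = FALSE)
      s <- summarize_peaks(st$callers$c, 2.5e6)
      expect_lte(s$peak_count, prev_count)
      expect_gte(s$bandwidth_mean, prev_bw - 1e-9)
      prev_count <- s$peak_count; prev_bw <- s$bandwidth_mean
    }
  }
})

test_that("false peaks never overlap true domains", {
  cfg <- small_cfg(seed = 13, caller_profiles = list(
    caller_profile("fp_only", sensitivity = 0, fp_per_mb = 10,
                   jitter_sd = 0, merge_gap = 0)))
  st <- simulate_study(cfg, tracks = FALSE)
  fp <- st$callers$fp_only
  expect_gt(n_peaks(fp), 0)
  td <- st$truth$true_domains$intervals
  for (i in seq_len(n_peaks(fp))) {
    iv <- fp$intervals[i, ]
    same <- td[td$chrom == iv$chrom, , drop = FALSE]
    expect_false(any(same$start < iv$end & iv$start < same$end))
  }
})

test_that("with repression_odds = 1 the association grid shows no systematic signal", {
  ## false-positive budget: across null seeds, the mean number of flagged
  ## cells at alpha = 0.01 among the 12 tests stays at or below 1
  n_flagged <- integer(30)
  for (i in seq_along(n_flagged)) {
    cfg <- sim_config(seed = 1000 + i, chrom_lengths = c(chrA = 4e6),
                      n_genes = 400, repression_odds = 1,
                      caller_profiles = identity_profile())
    st <- simulate_study(cfg, tracks = FALSE)
    lb <- classify_genes(st$genes, st$callers$identity)
    expr <- discretize_expression(compute_zscores(st$expression))
    tab <- build_contingency(
      lb, data.frame(gene_id = expr$gene_id, category = expr$category))
    n_flagged[i] <- sum(significance_report(tab, alpha = 0.01)$significant)
  }
  expect_lte(mean(n_flagged), 1)
})
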