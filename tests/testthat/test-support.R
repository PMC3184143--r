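test_that("two-interval support geometry is correct", {
  a <- peak_collection(data.frame(chrom = "chr1", start = 0, end = 100), "a")
  b <- peak_collection(data.frame(chrom = "chr1", start = 50, end = 150), "b")
  tr <- build_support_track(list(a, b), toy_genome(200))
  s <- as.integer(tr$support$chr1)
  expect_equal(s[1:50], rep(1L, 50))    # [0,50): a only
  expect_equal(s[51:100], rep(2L, 50))  # [50,100): both
  expect_equal(s[101:150], rep(1L, 50)) # [100,150): b only
  expect_equal(s[151:200], rep(0L, 50))
})

test_that("a single collection's support track is its union indicator", {
  set.seed(31)
  pc <- random_collection(2000, 10)
  tr <- build_support_track(list(pc), toy_genome(2000))
  expect_equal(as.integer(tr$support$chr1) == 1L,
               coverage_oracle(pc$intervals, 2000))
})

test_that("identical duplicate collections give 100% at support 2", {
  pc <- random_collection(1000, 5, "a")
  pc2 <- peak_collection(pc$intervals, "b")
  tr <- build_support_track(list(pc, pc2), toy_genome(1000))
  for (x in list(pc, pc2)) {
    pr <- support_profile(x, tr)
    expect_equal(pr$percent, c(0, 100))
  }
})

test_that("within-set overlapping peaks contribute support at most 1", {
  a <- peak_collection(data.frame(chrom = "chr1", start = c(0, 10),
                                  end = c(50, 60)), "a")
  b <- peak_collection(data.frame(chrom = "chr1", start = 100, end = 110), "b")
  tr <- build_support_track(list(a, b), toy_genome(200))
  expect_equal(max(as.integer(tr$support$chr1)[1:60]), 1L)
})

test_that("support track matches the per-base oracle on randomized collections", {
  set.seed(77)
  for (rep in 1:40) {
    len <- sample(500:5000, 1)
    K <- sample(2:4, 1)
    cols <- lapply(seq_len(K), function(i)
      random_collection(len, sample(1:15, 1), paste0("p", i)))
    tr <- build_support_track(cols, toy_genome(len))
    expect_equal(as.integer(tr$support$chr1), support_oracle(cols, len))
    ## profile percentages sum to 100 exactly before rounding
    for (pc in cols) {
      pr <- support_profile(pc, tr)
      expect_equal(sum(pr$percent), 100)
      expect_gte(min(pr$percent), 0)
    }
  }
})

test_that("support is invariant to the order of collections", {
  set.seed(55)
  cols <- lapply(1:4, function(i) random_collection(3000, 8, paste0("p", i)))
  t1 <- build_support_track(cols, toy_genome(3000))
  t2 <- build_support_track(rev(cols), toy_genome(3000))
  expect_identical(as.integer(t1$support$chr1), as.integer(t2$support$chr1))
})

test_that("the worked percentage example holds: 60 of 200 bp at support 2 is 30%", {
  ## program A identifies 200 bp total; 60 of them are also found by B
  a <- peak_collection(data.frame(chrom = "chr1", start = 0, end = 200), "a")
  b <- peak_collection(data.frame(chrom = "chr1", start = 0, end = 60), "b")
  tr <- build_support_track(list(a, b), toy_genome(300))
  pr <- support_profile(a, tr)
  expect_equal(pr$percent[pr$support == 2], 30)
  expect_equal(pr$percent[pr$support == 1], 70)
})

test_that("disjoint chromosome sets and empty programs are rejected", {
  a <- peak_collection(data.frame(chrom = "chr1", start = 0, end = 10), "a")
  b <- peak_collection(data.frame(chrom = "chr9", start = 0, end = 10), "b")
  expect_error(build_support_track(list(a, b)), "disjoint")
  e <- peak_collection(data.frame(chrom = character(), start = numeric(),
                                  end = numeric()), "e")
  tr <- build_support_track(list(a), genome_spec(c(chr1 = 100)))
  expect_error(support_profile(e, tr), "empty")
})

test_that("sensitivity-only callers match the binomial support expectation", {
  ## two jitter-free, fp-free callers with sensitivities s1, s2 over the
  ## same domains: a bp reported by caller 1 has support 2 iff caller 2
  ## also kept that domain, so E[percent at support 2] ~ 100 * s2
  s2 <- 0.6
  hits <- numeric(30)
  for (i in seq_along(hits)) {
    cfg <- sim_config(seed = 300 + i, chrom_lengths = c(chrA = 3e6),
                      n_genes = 300, mark_fraction = 0.4,
                      caller_profiles = list(
                        caller_profile("one", 1, 0, 0, 0),
                        caller_profile("two", s2, 0, 0, 0)))
    st <- simulate_study(cfg, tracks = FALSE)
    tr <- build_support_track(st$callers, st$genome)
    pr <- support_profile(st$callers$one, tr)
    hits[i] <- pr$percent[pr$support == 2]
  }
  expect_equal(mean(hits), 100 * s2, tolerance = 0.05)
})
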