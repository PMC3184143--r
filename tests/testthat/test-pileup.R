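toy_track <- function(...) pileup_track(data.frame(...))

test_that("normalization scales input to the ChIP total and leaves ChIP alone", {
  chip <- toy_track(chrom = "chr1", start = 0, end = 100, depth = 1)   # 100
  input <- toy_track(chrom = "chr1", start = 0, end = 50, depth = 1)   # 50
  nt <- normalize_tracks(chip, input)
  expect_equal(nt$input$steps$depth, 2)
  expect_equal(nt$input$total, chip$total, tolerance = 1e-9)
  expect_identical(nt$chip$steps, chip$steps)

  same <- normalize_tracks(chip, chip)
  expect_equal(same$input$steps, chip$steps)

  empty <- pileup_track(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), depth = numeric()))
  expect_error(normalize_tracks(chip, empty), "zero total")
})

test_that("peak height is max minus min depth with implicit-zero gaps", {
  flat <- toy_track(chrom = "chr1", start = 0, end = 100, depth = 7)
  pk <- list(chrom = "chr1", start = 10, end = 90)
  expect_equal(peak_height(pk, flat), 0)

  steps <- toy_track(chrom = "chr1", start = c(0, 30, 60),
                     end = c(30, 60, 100), depth = c(3, 12, 5))
  expect_equal(peak_height(list(chrom = "chr1", start = 0, end = 100), steps), 9)

  ## half-covered peak: implicit zero participates in the min
  half <- toy_track(chrom = "chr1", start = 0, end = 50, depth = 4)
  pk2 <- list(chrom = "chr1", start = 0, end = 100)
  expect_equal(peak_height(pk2, half), 4)
  expect_equal(peak_height(pk2, half, include_gaps = FALSE), 0)

  expect_error(peak_height(list(chrom = "chr1", start = 5, end = 5), flat),
               "zero-length")
})

test_that("height is invariant under a constant depth shift inside the peak", {
  set.seed(8)
  d <- sample(0:20, 10, replace = TRUE)
  tr <- toy_track(chrom = "chr1", start = seq(0, 90, 10),
                  end = seq(10, 100, 10), depth = d)
  tr_shift <- toy_track(chrom = "chr1", start = seq(0, 90, 10),
                        end = seq(10, 100, 10), depth = d + 5)
  pk <- list(chrom = "chr1", start = 0, end = 100)
  expect_equal(peak_height(pk, tr), peak_height(pk, tr_shift))
})

test_that("stepwise heights equal the per-base oracle on random tracks", {
  set.seed(71)
  for (rep in 1:30) {
    len <- 1000
    nstep <- sample(3:12, 1)
    bnd <- sort(sample(0:len, 2 * nstep))
    st <- data.frame(chrom = "chr1", start = bnd[seq(1, 2 * nstep, 2)],
                     end = bnd[seq(2, 2 * nstep, 2)],
                     depth = sample(0:30, nstep, replace = TRUE))
    st <- st[st$end > st$start, ]
    tr <- pileup_track(st)
    pc <- random_collection(len, 5)
    hr <- mean_peak_height(pc, tr)
    depth <- depth_oracle(tr, len)
    expected <- vapply(seq_len(n_peaks(pc)), function(i) {
      iv <- pc$intervals[i, ]
      win <- depth[(iv$start + 1):iv$end]
      max(win) - min(win)
    }, 0)
    expect_equal(hr$per_peak_heights, expected)
    expect_equal(hr$mean_height, mean(expected))
  }
})

test_that("mean height errors on an empty collection and handles singletons", {
  tr <- toy_track(chrom = "chr1", start = 0, end = 100, depth = 2)
  e <- peak_collection(data.frame(chrom = character(), start = numeric(),
                                  end = numeric()), "e")
  expect_error(mean_peak_height(e, tr), "empty")
  one <- peak_collection(data.frame(chrom = "chr1", start = 0, end = 50), "one")
  hr <- mean_peak_height(one, tr)
  expect_equal(hr$mean_height, peak_height(list(chrom = "chr1", start = 0,
                                                end = 50), tr))
})

test_that("identity-caller mean height matches the analytic Poisson range expectation", {
  ## domains carry Poisson(background * fold) depth per 10 bp bin; the
  ## expected per-peak height is E[max - min] of its bin count m
  lambda <- 2 * 8
  devs <- numeric(20)
  for (i in seq_along(devs)) {
    cfg <- sim_config(seed = 600 + i, chrom_lengths = c(chrA = 2e6),
                      n_genes = 150, background_depth = 2, enrichment_fold = 8,
                      caller_profiles = list(caller_profile("identity", 1, 0, 0, 0)))
    st <- simulate_study(cfg)
    hr <- mean_peak_height(st$callers$identity, st$chip)
    m <- (st$callers$identity$intervals$end -
            st$callers$identity$intervals$start) / cfg$bin_size
    expected <- mean(vapply(m, pois_range_mean, 0, lambda = lambda))
    devs[i] <- hr$mean_height - expected
  }
  se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 3 * se + 0.05)
})
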