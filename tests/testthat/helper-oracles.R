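## Brute-force oracles, kept deliberately independent of the package's
## stepwise/Rle implementations: everything here works on per-base vectors
## or explicit combinatorial sums.

# per-base TRUE/FALSE coverage of 0-based half-open intervals on [0, len)
coverage_oracle <- function(intervals, len) {
  covered <- logical(len)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    covered[(s + 1):e] <- TRUE
  }
  covered
}

# per-base support count across collections on a single chromosome
support_oracle <- function(collections, len, chrom = "chr1") {
  support <- integer(len)
  for (pc in collections) {
    iv <- pc$intervals[pc$intervals$chrom == chrom, , drop = FALSE]
    if (nrow(iv))
      support <- support + as.integer(coverage_oracle(iv, len))
  }
  support
}

# per-base depth vector of a pileup on one chromosome (implicit zeros)
depth_oracle <- function(track, len, chrom = "chr1") {
  depth <- numeric(len)
  st <- track$steps[track$steps$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(st)))
    depth[(st$start[i] + 1):st$end[i]] <- st$depth[i]
  depth
}

# upper-tail hypergeometric P(X >= k) by explicit combinatorial sum
hyper_tail_oracle <- function(k, K, n, N) {
  kk <- max(0, k):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# upper-tail binomial P(X >= k) by explicit pmf sum
binom_tail_oracle <- function(k, n, p) {
  kk <- k:n
  sum(choose(n, kk) * p^kk * (1 - p)^(n - kk))
}

# E[max - min] of m iid Poisson(lambda) variables, by CDF summation
pois_range_mean <- function(m, lambda) {
  kmax <- max(50, ceiling(lambda + 12 * sqrt(lambda)))
  kk <- 0:kmax
  F <- ppois(kk, lambda)
  e_max <- sum(1 - F^m)                     # sum_k P(max > k)
  e_min <- sum((1 - F)^m)                   # sum_k P(min > k)
  e_max - e_min
}

# random peak collection on a toy single-chromosome genome
random_collection <- function(len, n_peaks, program = "p",
                              max_width = NULL) {
  if (is.null(max_width)) max_width <- max(2, len %/% 5)
  w <- sample.int(max_width, n_peaks, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(len - wi, 1) - 1L, 0L)
  peak_collection(data.frame(chrom = "chr1", start = s, end = s + w),
                  program = program)
}

toy_genome <- function(len = 10000) genome_spec(c(chr1 = len))
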