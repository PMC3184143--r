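toy_inputs <- function() {
  labels <- data.frame(gene_id = c("g1", "g2"),
                       label = c("upstream", "none"))
  cats <- data.frame(gene_id = c("g1", "g2"),
                     category = c("low", "high"))
  list(labels = labels, cats = cats)
}

test_that("contingency tables place genes in the right cells with consistent marginals", {
  ti <- toy_inputs()
  tab <- build_contingency(ti$labels, ti$cats)
  expect_equal(tab["low", "upstream"], 1L)
  expect_equal(tab["high", "none"], 1L)
  expect_equal(sum(tab), 2L)
  expect_equal(rowSums(tab)[["low"]], 1L)

  ## permutation invariance
  tab2 <- build_contingency(ti$labels[2:1, ], ti$cats)
  expect_identical(tab, tab2)

  dup <- rbind(ti$labels, ti$labels[1, ])
  expect_error(build_contingency(dup, ti$cats), "duplicate")
})

test_that("genes missing from either input are excluded with a message", {
  labels <- data.frame(gene_id = c("g1", "g2", "g3"),
                       label = c("upstream", "none", "within"))
  cats <- data.frame(gene_id = c("g1", "g2"), category = c("low", "high"))
  expect_message(tab <- build_contingency(labels, cats), "excluded")
  expect_equal(sum(tab), 2L)
})

test_that("conditional probabilities divide by the label marginal", {
  tab <- matrix(0L, 3, 4, dimnames = list(c("high", "middle", "low"),
                                          c("within", "upstream",
                                            "downstream", "none")))
  tab["low", "upstream"] <- 5L
  tab["middle", "upstream"] <- 3L
  tab["high", "upstream"] <- 2L
  cp <- conditional_probabilities(tab)
  expect_equal(cp["low", "upstream"], 0.5)
  expect_equal(sum(cp[, "upstream"]), 1)
  expect_true(all(is.na(cp[, "none"]))) # zero marginal reported absent
})

test_that("hypergeometric upper tails match exhaustive enumeration for N <= 30", {
  set.seed(17)
  for (rep in 1:200) {
    N <- sample(5:30, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(K, n), 1)
    tab <- matrix(0L, 3, 4, dimnames = list(c("high", "middle", "low"),
                                            c("within", "upstream",
                                              "downstream", "none")))
    ## embed (N, K, n, k) into a 3 x 4 table
    tab["low", "upstream"] <- k
    tab["low", "none"] <- K - k
    tab["high", "upstream"] <- n - k
    tab["high", "none"] <- N - K - (n - k)
    if (any(tab < 0)) next
    p <- hypergeometric_cell_test(tab, "low", "upstream")
    expect_equal(p, hyper_tail_oracle(k, K, n, N), tolerance = 1e-10)
  }
})

test_that("the saturated cell has the closed-form point probability", {
  tab <- matrix(0L, 3, 4, dimnames = list(c("high", "middle", "low"),
                                          c("within", "upstream",
                                            "downstream", "none")))
  tab["low", "upstream"] <- 10L
  tab["high", "none"] <- 10L
  ## N = 20, K = 10, n = 10, k = 10 -> 1 / choose(20, 10)
  expect_equal(hypergeometric_cell_test(tab, "low", "upstream"),
               1 / choose(20, 10), tolerance = 1e-12)
})

test_that("a cell at its expectation is never flagged", {
  tab <- matrix(25L, 3, 4, dimnames = list(c("high", "middle", "low"),
                                           c("within", "upstream",
                                             "downstream", "none")))
  p <- hypergeometric_cell_test(tab, "low", "upstream")
  expect_gt(p, 0.3)
  expect_false(significance_report(tab)$significant[
    significance_report(tab)$expression == "low" &
      significance_report(tab)$label == "upstream"])
})

test_that("significance flags are monotone in alpha", {
  set.seed(40)
  tab <- matrix(rpois(12, 20), 3, 4,
                dimnames = list(c("high", "middle", "low"),
                                c("within", "upstream", "downstream", "none")))
  n1 <- sum(significance_report(tab, alpha = 0.001)$significant)
  n2 <- sum(significance_report(tab, alpha = 0.01)$significant)
  n3 <- sum(significance_report(tab, alpha = 0.1)$significant)
  expect_true(n1 <= n2 && n2 <= n3)
})

test_that("BY-adjusted grids are at least as conservative as raw grids", {
  set.seed(41)
  tab <- matrix(rpois(12, 30), 3, 4,
                dimnames = list(c("high", "middle", "low"),
                                c("within", "upstream", "downstream", "none")))
  raw <- significance_report(tab, alpha = 0.01)
  adj <- significance_report(tab, alpha = 0.01, adjust = "BY")
  expect_true(all(adj$p_adj >= adj$p))
  expect_lte(sum(adj$significant), sum(raw$significant))
})

test_that("per-cell type-I error stays at or below 0.02 on null tables", {
  ## labels and categories drawn independently; 1000 tables
  set.seed(2024)
  n_genes <- 500
  hits <- 0L; cells <- 0L
  for (rep in 1:1000) {
    lab <- sample(c("within", "upstream", "downstream", "none"), n_genes,
                  replace = TRUE, prob = c(0.2, 0.1, 0.1, 0.6))
    cat_ <- sample(c("high", "middle", "low"), n_genes, replace = TRUE,
                   prob = c(1 / 3, 1 / 3, 1 / 3))
    tab <- matrix(as.integer(base::table(factor(cat_, c("high", "middle", "low")),
                                         factor(lab, c("within", "upstream",
                                                       "downstream", "none")))),
                  3, 4, dimnames = list(c("high", "middle", "low"),
                                        c("within", "upstream", "downstream",
                                          "none")))
    ps <- vapply(c("within", "upstream", "downstream", "none"), function(l)
      vapply(c("high", "middle", "low"), function(e)
        hypergeometric_cell_test(tab, e, l), 0), numeric(3))
    hits <- hits + sum(ps < 0.01)
    cells <- cells + length(ps)
  }
  expect_lte(hits / cells, 0.02)
})

test_that("binomial genic test matches enumeration and closed forms", {
  set.seed(19)
  for (rep in 1:100) {
    n <- sample(1:25, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_genic_test(k, n, p0), binom_tail_oracle(k, n, p0),
                 tolerance = 1e-10)
  }
  expect_equal(binomial_genic_test(10, 10, 0.5), 2^-10)
  expect_gt(binomial_genic_test(5, 10, 0.5), 0.3) # null center
  expect_error(binomial_genic_test(5, 10, 1.5), "p0")
  expect_error(binomial_genic_test(11, 10, 0.5), "k_genic")
})
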