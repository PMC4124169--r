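nullish <- function(n = 200, seed = 1, mu = 50) {
  set.seed(seed)
  m <- matrix(rnbinom(n * 4, mu = mu, size = 20), n,
              dimnames = list(sprintf("g%04d", 1:n),
                              c("beta_1", "beta_2", "alpha_1", "alpha_2")))
  m
}
ba_groups <- factor(rep(c("beta", "alpha"), each = 2),
                    levels = c("beta", "alpha"))

test_that("size factors recover exact scalar multiples", {
  m <- nullish(seed = 2)
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1]))), c(1, 1))
  f <- size_factors(cbind(a = m[, 1], b = 2 * m[, 1]))
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(exp(mean(log(f))), 1)  # normalized to geometric mean 1
})

test_that("size factors track true library sizes within 5%", {
  set.seed(31)
  mu <- 2^rnorm(2000, 6, 1.5)
  lib <- c(1, 0.6, 1.7, 1.1)
  cnt <- sapply(lib, function(l) rnbinom(2000, mu = mu * l, size = 20))
  f <- size_factors(cnt)
  ratio <- (f / f[1]) / (lib / lib[1])
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("a table with no gene positive in all samples is an error", {
  m <- matrix(c(1, 0, 0, 2), 2)
  expect_error(size_factors(m), "filter")
})

test_that("BH q-values match the brute-force step-up procedure", {
  for (s in 1:500) {
    set.seed(s)
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bf_bh(p))
  }
  # and within nb_test output the invariant q >= p holds
  de <- nb_test(nullish(seed = 3), ba_groups)
  expect_true(all(de$q_value >= de$p_value, na.rm = TRUE))
})

test_that("swapping group labels negates folds and preserves p-values", {
  m <- nullish(seed = 4)
  m[1:10, 1:2] <- m[1:10, 1:2] * 30
  d1 <- nb_test(m, ba_groups)
  d2 <- nb_test(m, factor(as.character(ba_groups),
                          levels = c("alpha", "beta")))
  expect_equal(d1$log2_fold, -d2$log2_fold)
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$call, d2$call)  # enrichment direction is label-invariant
})

test_that("all-zero genes are excluded from testing and called ns", {
  m <- nullish(seed = 5)
  m[3, ] <- 0
  de <- nb_test(m, ba_groups)
  expect_true(is.na(de$p_value[3]))
  expect_equal(de$call[3], "ns")
  expect_equal(sum(!is.na(de$p_value)), nrow(m) - 1)
})

test_that("groups with fewer than two replicates are rejected", {
  m <- nullish(seed = 6)[, 1:3]
  expect_error(nb_test(m, factor(c("a", "b", "b"))), "2 replicates")
})

test_that("null simulation is calibrated at alpha = 0.05", {
  k <- simulate_null_counts(2000, seed = 101)
  de <- nb_test(k, ba_groups)
  frac <- mean(de$p_value < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  expect_equal(sum(de$p_value < 1e-7, na.rm = TRUE), 0)
})

test_that("planted 20-fold genes are detected under the stringent gate", {
  set.seed(7)
  mu <- 2^rnorm(500, 6, 1) * 400
  cnt <- sapply(1:4, function(s) rnbinom(500, mu = mu, size = 20))
  cnt[1:50, 1:2] <- sapply(1:2, function(s)
    rnbinom(50, mu = mu[1:50] * 20, size = 20))
  dimnames(cnt) <- list(sprintf("g%03d", 1:500),
                        c("beta_1", "beta_2", "alpha_1", "alpha_2"))
  de <- nb_test(cnt, ba_groups)
  expect_gte(mean(de$call[1:50] == "beta_enriched"), 0.9)
})

test_that("glucose ranking puts planted up-regulated lncRNAs on top", {
  set.seed(8)
  n <- 300
  ids <- c(sprintf("g%03d", 1:(n - 20)), sprintf("lnc%02d", 1:20))
  mu <- 2^rnorm(n, 6, 1) * 100
  low <- sapply(1:2, function(s) rnbinom(n, mu = mu, size = 20))
  hi_mu <- mu
  hi_mu[n - 19] <- mu[n - 19] * 10  # lnc01 up-regulated 10x
  high <- sapply(1:2, function(s) rnbinom(n, mu = hi_mu, size = 20))
  rownames(low) <- rownames(high) <- ids
  colnames(low) <- c("low_1", "low_2"); colnames(high) <- c("high_1",
                                                            "high_2")
  gr <- glucose_response(low, high, lnc_ids = grep("^lnc", ids,
                                                   value = TRUE))
  expect_lte(which(gr$gene_id == "lnc01"), ceiling(n / 10))
  expect_true(gr$is_lnc[gr$gene_id == "lnc01"])
  # identical inputs give all-zero folds
  same <- glucose_response(low, low)
  expect_equal(same$log2_fold, rep(0, n), ignore_attr = TRUE)
})
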