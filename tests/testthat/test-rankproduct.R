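test_that("outlierness ranks: descending values, index tie-break, permutation", {
  expect_equal(as.vector(outlierness_ranks(cbind(c(0.9, 0.1, 0.5)))),
               c(1L, 3L, 2L))
  expect_equal(as.vector(outlierness_ranks(cbind(c(0.5, 0.5)))), c(1L, 2L))
  set.seed(24)
  R <- outlierness_ranks(matrix(runif(200), 50, 4))
  for (j in 1:4) expect_setequal(R[, j], 1:50)
  expect_error(outlierness_ranks(matrix(c(1, NA), 2, 1)), "row 2, column 1")
})

test_that("rank products of the worked examples are exact integers", {
  expect_identical(rank_product(c(7, 3, 223)), 4683)
  expect_identical(rank_product(c(47, 125, 1)), 5875)
  expect_identical(rank_product(c(1, 28, 153)), 4284)
  expect_identical(rank_product(c(1, 1, 1)), 1)
  expect_error(rank_product(c(0, 2)), "positive integers")
})

test_that("exact p-values: tiny cases by hand and DP vs enumeration", {
  expect_equal(rp_pvalue_exact(1, 4, 2), 1 / 16)
  expect_equal(rp_pvalue_exact(4, 4, 2), 8 / 16)   # brute force: 8 pairs
  expect_equal(rp_pvalue_exact(16, 4, 2), 1)
  expect_error(rp_pvalue_exact(17, 4, 2), "range")

  for (n in c(3, 7)) {
    for (k in 2:3) {
      rho <- seq_len(n^k)
      expect_identical(rp_pvalue_exact(rho, n, k),
                       brute_rp_count(rho, n, k) / n^k)
    }
  }
})

test_that("counting function properties: monotone, boundary values", {
  n <- 9; k <- 3
  p <- rp_pvalue_exact(seq_len(n^k), n, k)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[1], 1 / n^k)
  expect_equal(p[n^k], 1)
})

test_that("bounds bracket the exact p-value; approximation is the geometric mean", {
  set.seed(25)
  for (n in c(10, 50)) {
    for (k in 2:4) {
      rps <- unique(pmin(round(exp(seq(0, k * log(n), length.out = 12))), n^k))
      ex <- rp_pvalue_exact(rps, n, k)
      b <- rp_pvalue_bounds(rps, n, k)
      expect_true(all(b$lower <= ex + 1e-12))
      expect_true(all(b$upper >= ex - 1e-12))
      expect_equal(b$approx, sqrt(b$lower * b$upper), tolerance = 1e-12)
    }
  }
  # whole sample space: all three equal 1
  b1 <- rp_pvalue_bounds(8^3, 8, 3)
  expect_equal(unlist(b1), c(lower = 1, upper = 1, approx = 1))
})

test_that("p-values are invariant to monotone transforms of each column", {
  set.seed(26)
  D <- matrix(runif(60), 20, 3)
  D2 <- cbind(exp(D[, 1]), D[, 2]^3, log1p(D[, 3]))
  t1 <- rp_test(D); t2 <- rp_test(D2)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$sample_id, t2$sample_id)
})

test_that("BH q-values match the by-hand example and are valid", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_error(fdr_bh(c(0.1, 0)), "0, 1")
  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")
  set.seed(27)
  p <- runif(50)
  q <- fdr_bh(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("rp_test: identical columns square the ranks; sorting is stable", {
  D <- cbind(c(0.2, 0.9, 0.5), c(0.2, 0.9, 0.5))
  tt <- rp_test(D)
  expect_equal(tt$rp, c(1, 4, 9))
  expect_equal(tt$sample_id, c("2", "3", "1"))
  expect_identical(attr(tt, "pvalue_engine"), "exact")
  expect_error(rp_test(cbind(1:3)), "at least 2 models")
})

test_that("the convolution engine brackets exact p-values at moderate k", {
  # n = 30, k = 8: n^k < 2^53, so the DP is still an available oracle
  n <- 30; k <- 8
  set.seed(28)
  R <- replicate(k, sample(n, 25))
  log_rp <- rowSums(log(R))
  ex <- rp_pvalue_exact(round(exp(log_rp)), n, k)
  cv <- rpoutliers:::rp_pvalue_conv(log_rp, n, k)
  ok <- !is.na(cv$lower)
  expect_true(any(ok))
  expect_true(all(cv$lower[ok] <= ex[ok] + 1e-9))
  expect_true(all(cv$upper[ok] >= ex[ok] - 1e-9))
})

test_that("null p-values are approximately uniform (independent noise)", {
  set.seed(29)
  crit <- 1.63 / sqrt(200)  # KS 1% critical value, n = 200
  ok <- replicate(60, {
    D <- matrix(runif(600), 200, 3)
    ks <- suppressWarnings(ks.test(rp_test(D)$p_value, "punif")$statistic)
    ks < crit
  })
  expect_gte(mean(ok), 0.95)
})
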