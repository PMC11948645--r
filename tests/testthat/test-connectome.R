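# FC construction, row thresholding, the normalized-angle kernel and the
# binarized positive graph.

test_that("compute_fc applies Fisher z with zero diagonal", {
  set.seed(1)
  ts <- matrix(rnorm(600), 200, 3)
  ts[, 2] <- 0.5 * ts[, 1] + sqrt(0.75) * ts[, 2]
  z <- compute_fc(ts)
  expect_symmetric(z)
  expect_true(all(diag(z) == 0))
  expect_equal(z[1, 2], atanh(cor(ts[, 1], ts[, 2])), tolerance = 1e-12)
  # atanh oracle at r = 0.5 (arbitrary-precision value)
  expect_equal(atanh(0.5), 0.549306144334055, tolerance = 1e-12)
})

test_that("perfect correlations are clamped with a warning", {
  ts <- matrix(rnorm(30), 10, 3)
  ts <- cbind(ts, ts[, 1])
  expect_warning(z <- compute_fc(ts), "clamped")
  expect_true(is.finite(z[1, 4]))
  expect_equal(z[1, 4], atanh(1 - 1e-7))
})

test_that("constant parcels error by default, listing the parcel", {
  ts <- matrix(rnorm(30), 10, 3)
  ts[, 2] <- 7
  expect_error(compute_fc(ts), "parcel\\(s\\): 2")
  expect_warning(z <- compute_fc(ts, on_constant = "zero"), "constant")
  expect_true(all(z[2, ] == 0))
})

test_that("row_threshold keeps the per-row quota with deterministic ties", {
  W <- matrix(rnorm(121), 11); diag(W) <- 0
  rt <- row_threshold(W, 0.10)           # ceiling(0.1 * 10) = 1
  expect_true(all(rowSums(rt != 0) == 1))
  # top value survives in each row
  for (i in 1:11) expect_equal(max(rt[i, ]), max(W[i, -i]))
  # ties break by column index
  Wt <- matrix(1, 5, 5); diag(Wt) <- 0
  rt2 <- row_threshold(Wt, 0.4)          # ceiling(0.4 * 4) = 2
  expect_equal(which(rt2[1, ] != 0), c(2L, 3L))
  # ceiling saturates at all off-diagonal entries
  rt3 <- row_threshold(matrix(rnorm(9), 3), 0.99)
  expect_true(all(rowSums(rt3 != 0) == 2))
  expect_error(row_threshold(W, 1.2), "density")
  # input untouched
  W2 <- matrix(rnorm(25), 5); W3 <- W2
  invisible(row_threshold(W2, 0.5))
  expect_identical(W2, W3)
})

test_that("normalized-angle kernel maps parallel/orthogonal/antiparallel", {
  W <- rbind(c(1, 0, 0, 2), c(2, 0, 0, 4), c(0, 3, 0, 0), c(-1, 0, 0, -2))
  A <- normalized_angle_affinity(W)
  expect_equal(A[1, 2], 1)          # identical direction
  expect_equal(A[1, 3], 0.5)        # orthogonal
  expect_equal(A[1, 4], 0)          # anti-parallel
  expect_true(all(diag(A) == 1))
  expect_symmetric(A)
  expect_error(normalized_angle_affinity(rbind(c(1, 1), c(0, 0))),
               "all-zero")
})

test_that("threshold + affinity chain is invariant to positive rescaling", {
  set.seed(7)
  W <- matrix(rnorm(400), 20); W <- (W + t(W)) / 2; diag(W) <- 0
  A1 <- normalized_angle_affinity(row_threshold(W, 0.2))
  A2 <- normalized_angle_affinity(row_threshold(3.7 * W, 0.2))
  expect_equal(A1, A2, tolerance = 1e-12)
})

test_that("binarize_positive_top keeps the global quota of positives", {
  W <- block_fc()
  A <- binarize_positive_top(W, 0.10)    # ceiling(0.1 * 45) = 5
  expect_equal(sum(A) / 2, 5)
  expect_symmetric(A)
  expect_true(all(diag(A) == 0))
  expect_true(all(W[A == 1] > 0))
  # dominant positive block captures all edges (brute-force ranking oracle)
  ut <- which(upper.tri(W))
  ord <- ut[order(-W[ut])]
  expect_setequal(which(upper.tri(W) & A == 1), ord[1:5])
  in_block <- outer(1:10 %in% 1:4, 1:10 %in% 1:4, `&`)
  expect_true(all(in_block[A == 1]))
  expect_error(binarize_positive_top(-abs(block_fc()), 0.1), "no positive")
  W2 <- W; W2[W2 > 0] <- 0; W2[1, 2] <- W2[2, 1] <- 0.5
  expect_warning(binarize_positive_top(W2, 0.10), "keeping all")
})
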