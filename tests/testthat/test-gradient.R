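# Diffusion-map embedding against a dense eigendecomposition oracle,
# template construction, and Procrustes alignment.

test_that("embedding eigenvalues match the dense oracle on random affinities", {
  set.seed(3)
  for (rep in 1:5) {
    A <- matrix(runif(900, 0.05, 1), 30)
    A <- (A + t(A)) / 2; diag(A) <- 1
    g <- diffusion_embedding(A, k = 6)
    # oracle: general (non-symmetric) eigendecomposition of the Markov
    # operator built independently
    d <- rowSums(A)
    W <- A / outer(sqrt(d), sqrt(d))          # alpha = 0.5
    M <- W / rowSums(W)
    ev <- sort(Re(eigen(M)$values), decreasing = TRUE)
    expect_equal(g$eigenvalues, ev[2:7], tolerance = 1e-8)
    # eigenvector check: components are right-eigenvectors of M
    for (j in 1:3) {
      v <- g$components[, j]
      expect_lt(max(abs(M %*% v - g$eigenvalues[j] * v)) / max(abs(v)),
                1e-8)
    }
    expect_true(all(diff(g$eigenvalues) <= 1e-12))
  }
})

test_that("two-block affinity separates blocks by component-1 sign", {
  B <- matrix(0.02, 20, 20)
  B[1:10, 1:10] <- 1; B[11:20, 11:20] <- 1; diag(B) <- 1
  g <- diffusion_embedding(B, k = 2)
  s <- sign(g$components[, 1])
  expect_true(all(s[1:10] == s[1]))
  expect_true(all(s[11:20] == -s[1]))
})

test_that("disconnected affinities and degenerate spectra are flagged", {
  A <- diag(6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1
  expect_error(diffusion_embedding(A, k = 2), "disconnected")
  # full symmetry: identity plus constant off-diagonal
  A2 <- matrix(0.5, 8, 8); diag(A2) <- 1
  expect_warning(diffusion_embedding(A2, k = 3), "degenerate")
})

test_that("embedding commutes with parcel relabeling", {
  set.seed(9)
  A <- matrix(runif(400, 0.1, 1), 20); A <- (A + t(A)) / 2; diag(A) <- 1
  perm <- sample(20)
  g1 <- diffusion_embedding(A, k = 3)
  g2 <- diffusion_embedding(A[perm, perm], k = 3)
  for (j in 1:3)
    expect_equal(abs(g2$components[, j]), abs(g1$components[perm, j]),
                 tolerance = 1e-8)
})

test_that("build_template averages matrices, not embeddings", {
  set.seed(5)
  mats <- replicate(4, {
    W <- matrix(rnorm(225), 15); W <- (W + t(W)) / 2; diag(W) <- 0; W
  }, simplify = FALSE)
  tpl <- build_template(mats, k = 3, density = 0.3)
  mean_fc <- Reduce(`+`, mats) / 4
  direct <- diffusion_embedding(
    normalized_angle_affinity(row_threshold(mean_fc, 0.3)), k = 3)
  expect_equal(tpl$components, direct$components, tolerance = 1e-12)
  # a single-subject list reproduces that subject's embedding
  tpl1 <- build_template(mats[1], k = 3, density = 0.3)
  solo <- diffusion_embedding(
    normalized_angle_affinity(row_threshold(mats[[1]], 0.3)), k = 3)
  expect_equal(tpl1$components, solo$components, tolerance = 1e-12)
  expect_error(build_template(list()), "non-empty")
})

test_that("template orients the sensory-DMN axis by the atlas", {
  atlas <- make_atlas(70)
  truth <- zero_noise_truth(atlas)
  coh <- simulate_cohort(6, 0, truth)
  sim <- simulate_cohort_connectivity(coh, truth, atlas)
  tpl <- build_template(sim$matrices, k = 3, atlas = atlas)
  expect_gt(mean(tpl$components[atlas$network_of == "DMN", 1]), 0)
  expect_lt(mean(tpl$components[atlas$network_of == "Visual", 1]), 0)
})

test_that("Procrustes recovers orthogonal transforms exactly", {
  set.seed(11)
  X <- matrix(rnorm(200), 20)
  # self-alignment is the identity
  expect_equal(procrustes_align(X, X), X, tolerance = 1e-12)
  # sign flips are orthogonal
  F <- diag(c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1))
  expect_equal(procrustes_align(X %*% F, X), X, tolerance = 1e-10)
  # random rotation from QR
  Q <- qr.Q(qr(matrix(rnorm(100), 10)))
  expect_lt(norm(procrustes_align(X %*% Q, X) - X, "F"), 1e-8)
  expect_error(procrustes_align(X[, 1:3], X), "mismatch")
})

test_that("alignment never increases the distance to the template", {
  set.seed(13)
  for (rep in 1:10) {
    X <- matrix(rnorm(120), 20)
    Tm <- matrix(rnorm(120), 20)
    d_before <- norm(X - Tm, "F")
    d_after <- norm(procrustes_align(X, Tm) - Tm, "F")
    expect_lte(d_after, d_before + 1e-12)
  }
})
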