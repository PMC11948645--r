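# Cohort generator contracts: determinism, ranges, planted structure.

test_that("atlas construction partitions parcels over 7 networks", {
  a <- make_atlas(14, network_sizes = rep(2, 7))
  expect_equal(as.integer(table(a$network_of)), rep(2L, 7))
  a200 <- make_atlas(200)
  expect_equal(sum(table(a200$network_of)), 200L)
  expect_true(all(table(a200$network_of) >= 1))
  expect_equal(length(unique(a200$parcel_id)), 200L)
  expect_error(make_atlas(5), "at least 7")
  expect_error(make_atlas(20, network_sizes = rep(2, 7)), "sum to P")
  # atlas round-trips through its TSV representation
  p <- tempfile(fileext = ".tsv")
  write_atlas(a200, p)
  back <- read_atlas(p)
  expect_equal(back$network_of, a200$network_of)
})

test_that("cohort tables respect sizes, ranges and determinism", {
  atlas <- make_atlas(21)
  truth <- sim_truth(atlas, seed = 5)
  coh <- simulate_cohort(100, 50, truth)
  expect_equal(nrow(coh), 150)
  expect_equal(sum(coh$group == "TD"), 100)
  expect_true(all(coh$age >= 5 & coh$age <= 22))
  expect_true(all(coh$sex %in% c("male", "female")))
  expect_identical(coh, simulate_cohort(100, 50, truth))
  expect_equal(nrow(simulate_cohort(0, 0, truth)), 0)
  # skewed option samples younger ages more densely
  sk <- simulate_cohort(400, 0, truth, age_dist = "skewed")
  expect_lt(median(sk$age), median(coh$age))
})

test_that("connectivity matrices are symmetric with planted structure", {
  atlas <- make_atlas(21)
  truth <- sim_truth(atlas, seed = 5)
  subj <- data.frame(age = 9, sex = "female", group = "ASD")
  W <- simulate_connectivity(subj, truth, atlas, seed = 7)
  expect_symmetric(W)
  expect_true(all(diag(W) == 0))
  expect_identical(W, simulate_connectivity(subj, truth, atlas, seed = 7))
  # degenerate mixture: no modules, no noise -> exact rank-1 off-diagonal
  tr0 <- zero_noise_truth(atlas)
  tr0$module_strength <- 0
  tr0$between_strength <- 0
  W0 <- simulate_connectivity(subj, tr0, atlas, seed = 7)
  g <- tr0$gradient_weight * attr(W0, "scale")^2 * atlas$P
  u <- attr(W0, "alignment")  # should be 1: direction is the template
  expect_equal(u, 1, tolerance = 1e-12)
  g0u <- tr0$template_gradient / sqrt(sum(tr0$template_gradient^2))
  R1 <- g * outer(g0u, g0u); diag(R1) <- 0
  expect_equal(unname(W0), unname(R1), tolerance = 1e-10,
               ignore_attr = TRUE)
  # leading eigenvector of the zero-noise matrix (rank-1 diagonal
  # restored) is exactly the planted axis
  W0full <- W0 + diag(g * g0u^2)
  ev <- eigen(W0full, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(cor(ev, g0u)), 1, tolerance = 1e-10)
})

test_that("ASD deviation is an inverted U peaking at the configured age", {
  atlas <- make_atlas(21)
  truth <- sim_truth(atlas, seed = 5, peak_age = 15)
  ages <- seq(5, 22, by = 0.25)
  d <- truth$deviation_fn(ages)
  expect_equal(ages[which.max(d)], 15)
  expect_true(all(d <= d[ages == 15] + 1e-12))
  # TD alignment strictly increases over the range
  expect_true(all(diff(truth$align_td(ages)) > 0))
})

test_that("group contrast at generator level: ASD below TD in childhood", {
  atlas <- make_atlas(70)
  truth <- sim_truth(atlas, seed = 11)
  coh <- simulate_cohort(120, 120, truth)
  sim <- simulate_cohort_connectivity(coh, truth, atlas)
  young <- coh$age < 12
  expect_gt(mean(sim$truth_table$alignment[young & coh$group == "TD"]),
            mean(sim$truth_table$alignment[young & coh$group == "ASD"]))
})

test_that("time series realize the target correlation structure", {
  expect_error(simulate_timeseries(diag(3) * 0, T = 1), ">= 2")
  # identity target: independent series
  Z <- matrix(0, 4, 4)
  X <- simulate_timeseries(Z, T = 4000, seed = 2)
  expect_lt(max(abs(cor(X)[upper.tri(diag(4))])), 0.08)
  expect_identical(X, simulate_timeseries(Z, T = 4000, seed = 2))
  # fixed z target recovered at large T (Monte-Carlo consistency)
  set.seed(4)
  R <- matrix(0.25, 6, 6) + diag(0.75, 6)
  Zt <- atanh(R); diag(Zt) <- 0
  Xl <- simulate_timeseries(Zt, T = 50000, seed = 9)
  expect_equal(attr(Xl, "shrinkage"), 0)
  expect_lt(max(abs(cor(Xl) - R)), 0.03)
  # and compute_fc recovers the z-matrix end to end
  Zhat <- compute_fc(Xl)
  expect_lt(max(abs(Zhat - Zt)), 0.03)
})

test_that("non-PD targets are shrunk minimally toward identity", {
  R <- matrix(0.99, 5, 5); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- -0.9     # makes it indefinite
  Z <- atanh(pmin(pmax(R, -0.999), 0.999)); diag(Z) <- 0
  X <- simulate_timeseries(Z, T = 100, seed = 1)
  w <- attr(X, "shrinkage")
  expect_gt(w, 0)
  # minimality: slightly less shrinkage is not positive definite
  R0 <- tanh(Z); diag(R0) <- 1
  lam <- function(w) min(eigen((1 - w) * R0 + w * diag(5),
                               symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(lam(w * 0.9), 1e-6)
})

test_that("symptom scores hit the target correlation", {
  atlas <- make_atlas(21)
  truth <- sim_truth(atlas, seed = 5)
  coh <- simulate_cohort(250, 250, truth)
  set.seed(8)
  align <- 0.9 + 0.05 * rnorm(500)
  s0 <- simulate_symptoms(coh, align, rho = 0, seed = 3)
  expect_lt(abs(cor(s0$srs_total, align)), 0.1)
  s5 <- simulate_symptoms(coh, align, rho = -0.5, seed = 3)
  expect_lt(abs(cor(s5$srs_total, align) + 0.5), 0.1)
  # exact rank reversal at rho = -1 with noiseless subscores
  s1 <- simulate_symptoms(coh, align, rho = -1, seed = 3,
                          subscore_noise_sd = 0)
  expect_equal(order(s1$srs_total), order(-align))
  expect_equal(cor(s1$srs_1, s1$srs_total), 1)
  expect_error(simulate_symptoms(coh, align, rho = -2), "rho")
})
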