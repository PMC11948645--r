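# Hierarchy score analytics, trajectory fitting, group comparisons,
# age bins, behavioral correlation.

test_that("hierarchy score analytic cases", {
  v <- c(1, -2, 3, 0.5)
  expect_equal(hierarchy_score(v, v), 1)
  expect_equal(hierarchy_score(2 * v, v), 1)           # scale invariance
  expect_equal(hierarchy_score(0.01 * v, 100 * v), 1)
  w <- c(2, 1, 0, 0); u <- c(-1, 2, 0, 0)              # orthogonal pair
  expect_equal(hierarchy_score(w, u), 0)
  expect_equal(hierarchy_score(v, -v), -1)             # antipodal
  expect_error(hierarchy_score(v, v[1:3]), "length")
  expect_error(hierarchy_score(v, rep(0, 4)), "zero")
})

test_that("score_cohort scores a subject on the median curve as 1", {
  set.seed(2)
  n <- 120; P <- 4
  age <- runif(n, 5, 22)
  Y <- vapply(1:P, function(j) 0.1 * j * age + rnorm(n, 0, 0.05),
              numeric(n))
  models <- fit_normative_set(Y, age, lambda = 10)
  cohort <- data.frame(subject_id = "x", age = 12)
  med <- vapply(models, normative_median_curve, numeric(1), age_grid = 12)
  sc <- score_cohort(matrix(med, 1), models, cohort)
  expect_equal(sc$score, 1, tolerance = 1e-10)
})

test_that("trajectory fit recovers planted linear trend and peak", {
  set.seed(7)
  n <- 400
  age <- runif(n, 5, 22)
  sex <- sample(c("male", "female"), n, TRUE)
  # linear trend 0.01/year
  sc_lin <- data.frame(score = 0.7 + 0.01 * age + rnorm(n, 0, 0.03),
                       age = age, sex = sex, group = "TD")
  tf <- fit_score_trajectory(sc_lin, group = "TD", lambda = 10)
  expect_lt(max(abs(tf$slopes - 0.01)), 0.003)
  expect_true(all(is.na(tf$peak_age)))        # monotone: no interior peak
  # inverted U peaking at 15
  sc_u <- data.frame(score = 0.9 - 0.001 * (age - 15)^2 + rnorm(n, 0, 0.02),
                     age = age, sex = sex, group = "ASD")
  tu <- fit_score_trajectory(sc_u, group = "ASD", lambda = 10)
  expect_lt(max(abs(tu$peak_age - 15)), 1.5)
  expect_true(all(tu$curves$lo <= tu$curves$median + 1e-12))
  expect_true(all(tu$curves$median <= tu$curves$hi + 1e-12))
  expect_error(fit_score_trajectory(sc_u, group = "TD"), "not present")
})

test_that("sigma_age_effect flags narrowing score spread", {
  set.seed(8)
  n <- 500
  age <- runif(n, 5, 22)
  sc <- data.frame(score = 0.9 + rnorm(n, 0, 0.06 - 0.002 * (age - 5)),
                   age = age, group = "TD")
  st <- sigma_age_effect(sc, group = "TD")
  expect_lt(st$p, 0.05)
  expect_equal(st$trend, -1)
})

test_that("compare_centiles: null identity and BH against a brute oracle", {
  A <- matrix(runif(60), 10, 6)
  expect_error(compare_centiles(A[1, , drop = FALSE], A), "at least 2")
  same <- compare_centiles(A, A)
  expect_true(all(same$t == 0))
  expect_true(all(same$q == 1))
  # brute-force BH step-up oracle on a fixed p-vector
  p <- c(0.01, 0.02, 0.03, 0.04)
  bh_brute <- function(p, q = 0.05) {
    o <- order(p); m <- length(p)
    k <- max(c(0, which(p[o] <= q * seq_len(m) / m)))
    rejected <- logical(m); if (k > 0) rejected[o[seq_len(k)]] <- TRUE
    rejected
  }
  expect_true(all(bh_brute(p)))             # all four rejected at q* = .05
  expect_true(all(p.adjust(p, "BH") <= 0.05))
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.04))
})

test_that("groups with a planted network shift show the matching t signs", {
  set.seed(9)
  atlas <- tiny_atlas(21)
  n <- 80
  base <- matrix(runif(n * 21, 0.3, 0.7), n, 21)
  shift <- base
  dmn <- which(atlas$network_of == "DMN")
  datt <- which(atlas$network_of == "DorsalAttention")
  shift[, dmn] <- shift[, dmn] - 0.15
  shift[, datt] <- shift[, datt] + 0.15
  cc <- compare_centiles(network_average_centiles(shift, atlas),
                         network_average_centiles(base, atlas))
  expect_lt(cc$t[cc$feature == "DMN"], 0)
  expect_gt(cc$t[cc$feature == "DorsalAttention"], 0)
  expect_lt(cc$q[cc$feature == "DMN"], 0.05)
})

test_that("age bins follow the half-open convention", {
  b <- assign_age_bin(c(5, 11.99, 12, 14.99, 15, 21.99, 22))
  expect_equal(as.character(b),
               c("5-12", "5-12", "12-15", "12-15", "15-22", "15-22",
                 "15-22"))
  expect_true(is.na(assign_age_bin(23)))
})

test_that("age_bin_analysis flags empty cells instead of failing", {
  set.seed(10)
  atlas <- tiny_atlas(21)
  n <- 40
  cohort <- data.frame(age = runif(n, 5, 11),    # children only
                       group = rep(c("TD", "ASD"), n / 2))
  cent <- matrix(runif(n * 21), n, 21)
  tab <- age_bin_analysis(cent, cohort, atlas)
  expect_true(all(is.na(tab$t[tab$bin != "5-12"])))
  expect_true(all(is.finite(tab$t[tab$bin == "5-12"])))
  expect_equal(nrow(tab), 21)  # 3 bins x 7 networks
})

test_that("behavior_correlation: perfect anticorrelation and FDR", {
  sc <- rnorm(50)
  sym <- data.frame(srs_total = -sc, srs_1 = rnorm(50))
  bc <- behavior_correlation(sc, sym)
  expect_equal(bc$r[bc$scale == "srs_total"], -1, tolerance = 1e-12)
  expect_equal(nrow(bc), 2)
  expect_true(all(bc$q >= bc$p - 1e-15))
  expect_error(behavior_correlation(sc, data.frame(a = rep(1, 50))),
               "constant")
  expect_error(behavior_correlation(sc[1:2], data.frame(a = rnorm(2))),
               "3 paired")
})
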