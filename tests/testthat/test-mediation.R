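# Standardized-path bootstrap mediation: algebraic identities, recovery
# of a planted chain, and null behavior.

test_that("c = c' + a*b and scale invariance hold exactly", {
  set.seed(1)
  n <- 200
  x <- rep(0:1, each = n / 2)
  m <- 0.5 * x + rnorm(n)
  y <- 0.3 * x + 0.4 * m + rnorm(n)
  r <- mediate(x, m, y, n_boot = 200, seed = 2)
  expect_equal(unname(r$paths["c"]),
               unname(r$paths["c_prime"] + r$paths["indirect"]),
               tolerance = 1e-10)
  # standardized paths are invariant to affine rescaling of m and y
  r2 <- mediate(x, 3 * m - 7, -2 * y + 1, n_boot = 200, seed = 2)
  expect_equal(unname(abs(r2$paths)), unname(abs(r$paths)),
               tolerance = 1e-10)
  expect_true(r$ci[1] <= r$paths["indirect"] &&
                r$paths["indirect"] <= r$ci[2])
})

test_that("a planted chain x -> m -> y is recovered", {
  set.seed(5)
  n <- 500
  x <- rep(0:1, each = n / 2)
  xs <- (x - mean(x)) / sd(x)
  m <- 0.5 * xs + sqrt(1 - 0.25) * rnorm(n)
  y <- 0.5 * (m - mean(m)) / sd(m) + sqrt(1 - 0.25) * rnorm(n)
  r <- mediate(x, m, y, n_boot = 2000, seed = 7)
  # indirect = a*b = 0.25 within simulation error (SE ~ 0.03 at n = 500)
  expect_lt(abs(r$paths["indirect"] - 0.25), 0.09)
  expect_gt(r$ci[1], 0)         # CI excludes zero
  expect_lt(r$p, 0.05)
  expect_lt(abs(r$paths["c_prime"]), 0.12)
})

test_that("null mediator gives coverage and determinism", {
  set.seed(11)
  n <- 120
  x <- rep(0:1, each = n / 2)
  covered <- logical(60)
  for (i in 1:60) {
    m <- rnorm(n); y <- 0.3 * x + rnorm(n)
    r <- mediate(x, m, y, n_boot = 400, seed = 1000 + i)
    covered[i] <- r$ci[1] <= 0 && 0 <= r$ci[2]
  }
  expect_gte(mean(covered), 0.85)
  m <- rnorm(n); y <- rnorm(n)
  r1 <- mediate(x, m, y, n_boot = 300, seed = 5)
  r2 <- mediate(x, m, y, n_boot = 300, seed = 5)
  expect_identical(r1$ci, r2$ci)
  expect_identical(r1$p, r2$p)
})

test_that("input validation catches degenerate designs", {
  x <- rep(0:1, 10)
  expect_error(mediate(x, rep(1, 20), rnorm(20)), "constant")
  expect_error(mediate(rep(1, 20), rnorm(20), rnorm(20)), "two levels")
  expect_error(mediate(x[1:5], rnorm(5), rnorm(5)), "at least 10")
  expect_error(mediate(x, rnorm(10), rnorm(20)), "equal length")
})

test_that("mediation_by_stage flags empty cells and adjusts per bin", {
  set.seed(3)
  n <- 120
  cohort <- data.frame(age = runif(n, 5, 11.5),   # only bin 1 populated
                       group = rep(c("TD", "ASD"), each = n / 2))
  pc <- matrix(rnorm(n * 2), n, 2,
               dimnames = list(NULL, c("WholeBrain", "DMN")))
  sc <- rnorm(n)
  tab <- mediation_by_stage(pc, sc, cohort, n_boot = 100, seed = 4)
  expect_true(all(is.na(tab$indirect[tab$bin == "12-15"])))
  expect_true(all(!is.na(tab$indirect[tab$bin == "5-12"])))
  expect_true(all(is.na(tab$q[tab$mediator == "WholeBrain"])))
})

test_that("stagewise mediation is invariant to group-label representation", {
  set.seed(12)
  n <- 80
  cohort_f <- data.frame(age = runif(n, 5, 11),
                         group = factor(rep(c("TD", "ASD"), each = n / 2),
                                        levels = c("TD", "ASD")))
  cohort_c <- cohort_f
  cohort_c$group <- as.character(cohort_c$group)   # CSV round-trip form
  pc <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "DMN"))
  sc <- rnorm(n)
  t1 <- mediation_by_stage(pc, sc, cohort_f, n_boot = 100, seed = 5)
  t2 <- mediation_by_stage(pc, sc, cohort_c, n_boot = 100, seed = 5)
  expect_identical(t1$a, t2$a)
  expect_identical(t1$indirect, t2$indirect)
})
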