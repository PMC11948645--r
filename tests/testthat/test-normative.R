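# SHASH normative fitting: recovery of planted location/scale curves,
# transfer recalibration, centile calibration, and the LR tests.

fit_cache <- new.env()

sim_sine <- function(n = 1000, seed = 1) {
  set.seed(seed)
  age <- runif(n, 5, 22)
  list(age = age, y = sin(age / 3) + rnorm(n, 0, 0.1))
}

test_that("planted smooth location curve is recovered", {
  d <- sim_sine()
  m <- fit_normative(d$y, d$age, lambda = 1)
  fit_cache$sine <- list(m = m, d = d)
  grid <- seq(5.85, 21.15, length.out = 60)   # interior 90% of the range
  rmse <- sqrt(mean((normative_median_curve(m, grid) - sin(grid / 3))^2))
  expect_lt(rmse, 0.05)
  expect_true(m$converged)
  # monotone planted trend gives monotone recovered median
  set.seed(2)
  age2 <- runif(800, 5, 22)
  y2 <- 0.05 * age2 + rnorm(800, 0, 0.05)
  m2 <- fit_normative(y2, age2, lambda = 10)
  med2 <- normative_median_curve(m2, seq(6, 21, length.out = 50))
  expect_true(all(diff(med2) > -1e-4))
})

test_that("null data fit is flat with Gaussian shape", {
  set.seed(6)
  n <- 2000
  age <- runif(n, 5, 22)
  y <- rnorm(n)
  m <- fit_normative(y, age)
  p <- predict(m, seq(5, 22, length.out = 40))
  # flatness tolerance = 3 SE of the unpenalized linear null-space
  # component (slope SE ~ sd(y) / (sd(age) sqrt(n)) over the 17 y range)
  tol <- 3 * 17 / (sd(age) * sqrt(n))
  expect_lt(diff(range(p$mu)), 2 * tol)
  expect_lt(p$nu[1], 0.15)            # log link: nu ~ 0 means no skew
  expect_lt(abs(p$tau[1] - 1), 0.15)
  # SHASH optimum is at least as good as the Gaussian special case
  mg <- fit_normative(y, age, lambda = m$lambda, estimate_shape = FALSE)
  expect_gte(m$loglik, mg$loglik - 1e-6)
})

test_that("planted log-sigma slope is recovered within 30%", {
  set.seed(2)
  n <- 2000
  age <- runif(n, 5, 22)
  y <- 0.5 * age + rshash(n, 0, exp(-3 + 0.05 * age), 0, 1)
  m <- fit_normative(y, age, lambda = 1)
  sg <- predict(m, c(6, 21))$sigma
  slope <- (log(sg[2]) - log(sg[1])) / 15
  expect_lt(abs(slope - 0.05), 0.015)
})

test_that("centiles are uniform under the fitted model (PIT)", {
  d <- fit_cache$sine$d; m <- fit_cache$sine$m
  set.seed(3)
  idx <- 1:500
  p <- predict(m, d$age[idx])
  ynew <- rshash(500, p$mu, p$sigma, p$nu, p$tau)
  cs <- centile_scores(m, ynew, d$age[idx])
  ks <- suppressWarnings(ks.test(cs, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
  # subject exactly on the median curve scores 0.5
  med <- normative_median_curve(m, d$age[1:5])
  expect_equal(unname(centile_scores(m, med, d$age[1:5])),
               rep(0.5, 5), tolerance = 1e-10)
  expect_warning(cs_inf <- centile_scores(m, 1e6, d$age[1]), "clipped")
  expect_equal(unname(cs_inf), 1 - 1e-6)
})

test_that("quantile-median identity holds on the fitted model", {
  m <- fit_cache$sine$m
  p <- predict(m, c(7, 12, 19))
  med <- qshash(0.5, p$mu, p$sigma, p$nu, p$tau)
  expect_equal(pshash(med, p$mu, p$sigma, p$nu, p$tau), rep(0.5, 3),
               tolerance = 1e-10)
})

test_that("transfer recalibration recovers location and scale shifts", {
  d <- fit_cache$sine$d; m <- fit_cache$sine$m
  self <- transfer_recalibrate(m, d$y, d$age)
  expect_lt(max(abs(self$transfer_shift)), 1e-3)
  up2 <- transfer_recalibrate(m, d$y + 2, d$age)
  expect_equal(unname(up2$transfer_shift["mu"]), 2, tolerance = 0.01)
  expect_lt(abs(up2$transfer_shift["log_sigma"]), 0.05)
  # pure scale change on a flat-location feature
  set.seed(9)
  n <- 1000; age <- runif(n, 5, 22); yf <- rnorm(n, 3, 0.5)
  mf <- fit_normative(yf, age, lambda = 10)
  dbl <- transfer_recalibrate(mf, mean(yf) + 2 * (yf - mean(yf)), age)
  expect_equal(unname(dbl$transfer_shift["log_sigma"]), log(2),
               tolerance = 0.05)
  expect_lt(abs(dbl$transfer_shift["mu"]), 0.05)
  # transfer onto an identically distributed cohort keeps centiles uniform
  set.seed(10)
  p <- predict(m, d$age[1:500])
  ynew <- rshash(500, p$mu, p$sigma, p$nu, p$tau)
  tr <- transfer_recalibrate(m, ynew, d$age[1:500])
  ks <- suppressWarnings(
    ks.test(centile_scores(tr, ynew, d$age[1:500]), "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("centile scores are invariant to common affine transforms", {
  d <- sim_sine(n = 400, seed = 13)
  m1 <- fit_normative(d$y, d$age, lambda = 1)
  m2 <- fit_normative(5 - 3 * d$y, d$age, lambda = 1)
  c1 <- centile_scores(m1, d$y[1:50], d$age[1:50])
  c2 <- centile_scores(m2, 5 - 3 * d$y[1:50], d$age[1:50])
  expect_equal(unname(c2), unname(1 - c1), tolerance = 5e-3)
})

test_that("age-effect LR test has power and respects nesting", {
  d <- fit_cache$sine$d; m <- fit_cache$sine$m
  at <- age_effect_test(m, d$y, d$age)
  expect_gte(at$statistic, 0)
  expect_lt(at$p, 1e-4)
  # sigma trend test detects a planted narrowing
  set.seed(4)
  n <- 500
  age <- runif(n, 5, 22)
  y <- rnorm(n, 0, exp(-1 - 0.05 * (age - 5)))
  m2 <- fit_normative(y, age, lambda = 10)
  st <- sigma_age_test(m2, y, age)
  expect_lt(st$p, 0.05)
  expect_equal(st$trend, -1)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_normative(rnorm(10), runif(10, 5, 22)), "at least 50")
  expect_error(fit_normative(rnorm(100), rep(7, 100), min_n = 50),
               "constant")
  expect_error(fit_normative(rep(1, 100), runif(100, 5, 22)),
               "constant")
})

test_that("sex-specific smooth deviation is recovered", {
  set.seed(15)
  n <- 1200
  age <- runif(n, 5, 22)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  y <- 0.1 * age + ifelse(sex == "male", 0.05 * (age - 5), 0) +
    rnorm(n, 0, 0.2)
  m <- fit_normative(y, age, sex, lambda = 10)
  gm <- normative_median_curve(m, c(10, 18), "male")
  gf <- normative_median_curve(m, c(10, 18), "female")
  gap <- (gm - gf)
  expect_equal(gap[1], 0.05 * 5, tolerance = 0.06)
  expect_equal(gap[2], 0.05 * 13, tolerance = 0.06)
})

test_that("models round-trip through the JSON serialization", {
  d <- sim_sine(n = 300, seed = 21)
  sex <- rep(c("male", "female"), 150)
  m <- fit_normative(d$y, d$age, sex, lambda = 10)
  p <- tempfile(fileext = ".json")
  write_normative(m, p)
  back <- read_normative(p)
  grid <- seq(6, 21, length.out = 20)
  sx <- rep("female", 20)
  expect_equal(predict(back, grid, sx), predict(m, grid, sx),
               tolerance = 1e-12)
  cs1 <- centile_scores(m, d$y[1:20], d$age[1:20], sex[1:20])
  cs2 <- centile_scores(back, d$y[1:20], d$age[1:20], sex[1:20])
  expect_equal(cs2, cs1, tolerance = 1e-12)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(read_normative(bad), "not a serialized")
})
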