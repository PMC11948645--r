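# Small deterministic fixtures shared across test files.

tiny_atlas <- function(P = 21) make_atlas(P, network_sizes = rep(P / 7, 7))

# a symmetric Fisher-z matrix with a planted positive block
block_fc <- function(P = 10, block = 1:4, hi = 1, lo = -0.2, seed = 1) {
  set.seed(seed)
  W <- matrix(lo + 0.05 * rnorm(P * P), P)
  W <- (W + t(W)) / 2
  W[block, block] <- hi
  diag(W) <- 0
  W
}

# noise-free truth: every subject expresses the template axis exactly
zero_noise_truth <- function(atlas, seed = 11) {
  sim_truth(atlas,
            axis_noise_base = 0, axis_noise_slope = 0,
            axis_sd_td0 = 0, axis_sd_td_slope = 0, axis_sd_asd = 0,
            dev_curv = 0, atten_curv = 0, med_base = 0, med_load = 0,
            med_beta = 0, module_jitter_sd = 0, noise_sd = 0,
            seed = seed)
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m))), tol)
}
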