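#' The sinh-arcsinh (SHASH) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the four-parameter sinh-arcsinh distribution with location `mu`,
#' scale `sigma > 0`, skewness `nu` and tail weight `tau > 0`.
#'
#' With `z = (x - mu) / sigma` the distribution function is
#' `F(x) = Phi(sinh(tau * asinh(z) - nu))` where `Phi` is the standard
#' normal CDF. At `nu = 0`, `tau = 1` the family reduces exactly to
#' `Normal(mu, sigma)`. `nu > 0` skews to the right, `tau < 1` fattens the
#' tails. The quantile function is available in closed form, so
#' `qshash(pshash(x)) == x` holds to numerical round-off.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu location parameter.
#' @param sigma scale parameter, strictly positive.
#' @param nu skewness parameter.
#' @param tau tail-weight parameter, strictly positive.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are given
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   `P[X <= x]`.
#' @return `dshash` gives the density, `pshash` the distribution function,
#'   `qshash` the quantile function and `rshash` random deviates.
#' @examples
#' pshash(0, mu = 0, sigma = 1, nu = 0, tau = 1)   # 0.5, Gaussian median
#' qshash(0.975, 0, 1, 0, 1)                        # 1.959964
#' @name shash
NULL

.check_shash <- function(sigma, tau) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("'tau' must be finite and > 0", call. = FALSE)
}

# numerically stable log(cosh(w))
.logcosh <- function(w) {
  aw <- abs(w)
  aw + log1p(exp(-2 * aw)) - log(2)
}

#' @rdname shash
#' @export
dshash <- function(x, mu = 0, sigma = 1, nu = 0, tau = 1, log = FALSE) {
  .check_shash(sigma, tau)
  z <- (x - mu) / sigma
  w <- tau * asinh(z) - nu
  r <- sinh(w)
  lp <- stats::dnorm(r, log = TRUE) + .logcosh(w) + log(tau) - log(sigma) -
    0.5 * log1p(z^2)
  if (log) lp else exp(lp)
}

#' @rdname shash
#' @export
pshash <- function(q, mu = 0, sigma = 1, nu = 0, tau = 1,
                   lower.tail = TRUE, log.p = FALSE) {
  .check_shash(sigma, tau)
  z <- (q - mu) / sigma
  r <- sinh(tau * asinh(z) - nu)
  stats::pnorm(r, lower.tail = lower.tail, log.p = log.p)
}

#' @rdname shash
#' @export
qshash <- function(p, mu = 0, sigma = 1, nu = 0, tau = 1,
                   lower.tail = TRUE, log.p = FALSE) {
  .check_shash(sigma, tau)
  r <- stats::qnorm(p, lower.tail = lower.tail, log.p = log.p)
  z <- sinh((asinh(r) + nu) / tau)
  mu + sigma * z
}

#' @rdname shash
#' @export
rshash <- function(n, mu = 0, sigma = 1, nu = 0, tau = 1) {
  qshash(stats::runif(n), mu = mu, sigma = sigma, nu = nu, tau = tau)
}

# ---- internal derivatives used by the penalized-likelihood fitter ----

# d loglik / dz at z = (y-mu)/sigma, per observation
.shash_dldz <- function(z, nu, tau) {
  w <- pmin(pmax(tau * asinh(z) - nu, -150), 150)
  s <- sqrt(1 + z^2)
  r <- sinh(w)
  tau / s * (tanh(w) - r * cosh(w)) - z / (1 + z^2)
}

# per-observation log-likelihood
.shash_ll <- function(z, sigma, nu, tau) {
  w <- pmin(pmax(tau * asinh(z) - nu, -150), 150)
  r <- sinh(w)
  -0.5 * r^2 - 0.5 * log(2 * pi) + .logcosh(w) + log(tau) - log(sigma) -
    0.5 * log1p(z^2)
}

# d loglik / d nu and d loglik / d log(tau)
.shash_dldnu <- function(z, nu, tau) {
  w <- pmin(pmax(tau * asinh(z) - nu, -150), 150)
  sinh(w) * cosh(w) - tanh(w)
}

.shash_dldlogtau <- function(z, nu, tau) {
  w <- pmin(pmax(tau * asinh(z) - nu, -150), 150)
  (tanh(w) - sinh(w) * cosh(w)) * tau * asinh(z) + 1
}
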