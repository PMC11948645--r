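#' Fit a SHASH normative model of age (and sex) for one feature
#'
#' Fits a generalized additive model for location, scale and shape in which
#' the feature follows a sinh-arcsinh (SHASH) distribution whose location
#' depends smoothly on age (plus a sex-specific smooth deviation), whose
#' log-scale depends smoothly on age, and whose skewness and tail-weight
#' parameters are constants:
#' \deqn{y \sim SHASH(\mu, \sigma, \nu, \tau)}
#' \deqn{\mu = \beta_\mu + f_{age}(age) + sex \cdot f_{age \times sex}(age)}
#' \deqn{\log\sigma = \beta_\sigma + g_{age}(age), \quad
#'       \log\nu \ (or\ \nu) = \beta_\nu, \quad \log\tau = \beta_\tau}
#' The smooths are P-splines: cubic B-splines on equally spaced interior
#' knots with a second-order difference penalty. Estimation is block-wise
#' penalized maximum likelihood (location block, scale block, shape block,
#' cycled with BFGS inner steps) from a deterministic initialization, so
#' refits are bit-reproducible. The smoothing weight is either fixed or
#' chosen from a small grid by generalized AIC.
#'
#' @param y numeric vector, the feature (one brain feature per model).
#' @param age numeric vector of ages in years.
#' @param sex optional factor/character with two levels (e.g. male/female);
#'   enables the sex-specific smooth on `mu`.
#' @param n_knots number of interior knots of the age basis.
#' @param degree B-spline degree (3 = cubic).
#' @param penalty_order difference-penalty order.
#' @param lambda smoothing weight; `NULL` (default) selects from
#'   `lambda_grid` by generalized AIC with penalty multiplier `gaic_k`.
#' @param lambda_grid candidate smoothing weights.
#' @param gaic_k GAIC penalty per effective degree of freedom.
#' @param nu_link link for the skewness parameter: `"log"` (as printed in
#'   the model specification, forcing nu > 0) or `"identity"`.
#' @param mu_age,sigma_age logicals; include the age smooth in the location
#'   / log-scale predictor.
#' @param mu_sex logical; include the sex-by-age varying-coefficient smooth
#'   (ignored when `sex` is `NULL` or has fewer than two levels).
#' @param estimate_shape logical; if `FALSE`, nu and tau are held at their
#'   Gaussian values (nu = 0 identity link, tau = 1).
#' @param min_n minimum sample size.
#' @param max_outer maximum outer block cycles.
#' @param tol convergence tolerance on the penalized log-likelihood.
#' @param age_range fitting range; defaults to the observed range.
#' @return an object of class `normative_model` with coefficient blocks,
#'   effective degrees of freedom, log-likelihood and fit metadata.
#' @seealso [predict.normative_model()], [centile_scores()],
#'   [transfer_recalibrate()], [normative_median_curve()],
#'   [age_effect_test()]
#' @export
fit_normative <- function(y, age, sex = NULL,
                          n_knots = 10, degree = 3, penalty_order = 2,
                          lambda = NULL, lambda_grid = c(0.1, 1, 10, 100),
                          gaic_k = 3, nu_link = c("log", "identity"),
                          mu_age = TRUE, mu_sex = !is.null(sex),
                          sigma_age = TRUE, estimate_shape = TRUE,
                          min_n = 50, max_outer = 200, tol = 1e-6,
                          age_range = NULL) {
  nu_link <- match.arg(nu_link)
  ok <- is.finite(y) & is.finite(age)
  y <- y[ok]; age <- age[ok]
  if (!is.null(sex)) sex <- sex[ok]
  n <- length(y)
  if (n < min_n)
    stop(sprintf("need at least %d observations, got %d", min_n, n),
         call. = FALSE)
  if (mu_age && stats::sd(age) == 0)
    stop("age is constant; cannot model an age effect", call. = FALSE)
  sex_levels <- NULL
  if (!is.null(sex)) {
    sex_levels <- sort(unique(as.character(sex)))
    if (length(sex_levels) < 2) mu_sex <- FALSE
  } else mu_sex <- FALSE
  if (is.null(age_range)) age_range <- range(age)
  # cap the basis size for small samples: an interpolating basis lets
  # sigma collapse toward zero (degenerate likelihood)
  n_knots <- min(n_knots, max(4L, n - degree - 3L))

  spec <- list(
    n_knots = n_knots, degree = degree, penalty_order = penalty_order,
    nu_link = nu_link, mu_age = mu_age, mu_sex = mu_sex,
    sigma_age = sigma_age, estimate_shape = estimate_shape,
    gaic_k = gaic_k, age_range = age_range, sex_levels = sex_levels
  )
  spec$knots <- .ps_knots(age_range, n_knots, degree)
  B <- .ps_eval(age, spec$knots, degree)
  spec$Z <- .ps_center(colSums(B))

  # fit on the standardized response for optimizer conditioning; the SHASH
  # family is location-scale equivariant so coefficients transform exactly
  ctr <- mean(y); scl <- stats::sd(y)
  if (!is.finite(scl) || scl == 0)
    stop("response is constant; cannot fit a distributional model",
         call. = FALSE)
  ys <- (y - ctr) / scl

  if (!is.null(lambda)) {
    fit <- .nm_fit(ys, age, sex, spec, lambda, max_outer, tol)
  } else {
    best <- NULL; warm <- NULL
    for (lam in lambda_grid) {
      f <- .nm_fit(ys, age, sex, spec, lam, max_outer, tol, init = warm)
      f$gaic <- -2 * f$loglik + gaic_k * f$edf_total
      warm <- f$coef
      if (is.null(best) || f$gaic < best$gaic) best <- f
    }
    fit <- best
  }
  # back-transform to the original response scale
  fit$coef$beta_mu <- fit$coef$beta_mu * scl
  fit$coef$beta_mu[1] <- fit$coef$beta_mu[1] + ctr
  fit$coef$beta_sigma[1] <- fit$coef$beta_sigma[1] + log(scl)
  fit$loglik <- fit$loglik - n * log(scl)
  fit$pen_loglik <- fit$pen_loglik - n * log(scl)
  fit$standardization <- c(center = ctr, scale = scl)
  fit$call_n <- n
  fit$transfer <- FALSE
  class(fit) <- "normative_model"
  fit
}

# ---- design construction (shared between fit, predict, transfer) ----

.nm_designs <- function(spec, age, sex) {
  n <- length(age)
  B <- .ps_eval(age, spec$knots, spec$degree)
  p <- ncol(B)
  S <- .ps_penalty(p, spec$penalty_order)
  Sc <- crossprod(spec$Z, S %*% spec$Z)

  Xm <- matrix(1, n, 1); Pm_blocks <- list(matrix(0, 1, 1))
  term_mu <- list(intercept = 1L)
  if (spec$mu_age) {
    Xm <- cbind(Xm, B %*% spec$Z)
    term_mu$age <- 1L + seq_len(p - 1)
    Pm_blocks <- c(Pm_blocks, list(Sc))
  }
  if (spec$mu_sex) {
    ind <- as.numeric(as.character(sex) == spec$sex_levels[2])
    Xm <- cbind(Xm, ind * B)
    term_mu$age_sex <- ncol(Xm) - p + seq_len(p)
    Pm_blocks <- c(Pm_blocks, list(S))
  }
  Xs <- matrix(1, n, 1); Ps_blocks <- list(matrix(0, 1, 1))
  term_sg <- list(intercept = 1L)
  if (spec$sigma_age) {
    Xs <- cbind(Xs, B %*% spec$Z)
    term_sg$age <- 1L + seq_len(p - 1)
    Ps_blocks <- c(Ps_blocks, list(Sc))
  }
  bdiag <- function(blocks) {
    sizes <- vapply(blocks, nrow, 1L)
    M <- matrix(0, sum(sizes), sum(sizes))
    at <- 0L
    for (b in blocks) {
      idx <- at + seq_len(nrow(b)); M[idx, idx] <- b; at <- at + nrow(b)
    }
    M
  }
  list(Xm = Xm, Xs = Xs, Pm = bdiag(Pm_blocks), Ps = bdiag(Ps_blocks),
       term_mu = term_mu, term_sg = term_sg)
}

.nm_nu <- function(bn, link) if (link == "log") exp(bn) else bn

# ---- the block-wise penalized ML engine ----

.nm_fit <- function(y, age, sex, spec, lambda, max_outer, tol, init = NULL) {
  d <- .nm_designs(spec, age, sex)
  Xm <- d$Xm; Xs <- d$Xs
  Pm <- lambda * d$Pm; Ps <- lambda * d$Ps
  pm <- ncol(Xm); ps <- ncol(Xs)
  big <- 1e12

  if (is.null(init)) {
    bm <- tryCatch(
      solve(crossprod(Xm) + Pm + diag(1e-8, pm), crossprod(Xm, y)),
      error = function(e) matrix(c(mean(y), rep(0, pm - 1))))
    bm <- as.numeric(bm)
    res_sd <- max(stats::sd(y - Xm %*% bm), 1e-6)
    bs <- c(log(res_sd), rep(0, ps - 1))
    bn <- if (spec$nu_link == "log") -6 else 0
    bt <- 0
  } else {
    bm <- init$beta_mu; bs <- init$beta_sigma
    bn <- init$beta_nu; bt <- init$beta_tau
  }
  if (!spec$estimate_shape) {
    bn <- if (spec$nu_link == "log") -Inf else 0
    bt <- 0
  }

  # a weak ridge on log-tau guards against the spike degeneracy that
  # heavily tied responses induce (sigma, tau jointly collapsing to zero)
  tau_ridge <- 1e-3
  pen <- function(bm, bs, bt = 0)
    0.5 * (sum(bm * (Pm %*% bm)) + sum(bs * (Ps %*% bs)) +
             tau_ridge * bt^2)
  state <- function(bm, bs, bn, bt) {
    mu <- as.numeric(Xm %*% bm)
    eta <- pmin(pmax(as.numeric(Xs %*% bs), -30), 30)
    sigma <- exp(eta)
    nu <- if (spec$estimate_shape) .nm_nu(bn, spec$nu_link) else 0
    tau <- if (spec$estimate_shape) exp(bt) else 1
    z <- (y - mu) / sigma
    list(mu = mu, sigma = sigma, nu = nu, tau = tau, z = z, eta = eta)
  }
  pll <- function(bm, bs, bn, bt) {
    s <- state(bm, bs, bn, bt)
    ll <- sum(.shash_ll(s$z, s$sigma, s$nu, s$tau))
    if (!is.finite(ll)) return(-big)
    ll - pen(bm, bs, bt)
  }

  fn_mu <- function(b) {
    s <- state(b, bs, bn, bt)
    ll <- sum(.shash_ll(s$z, s$sigma, s$nu, s$tau))
    if (!is.finite(ll)) return(big)
    -ll + pen(b, bs)
  }
  gr_mu <- function(b) {
    s <- state(b, bs, bn, bt)
    g <- .shash_dldz(s$z, s$nu, s$tau) / s$sigma
    out <- as.numeric(crossprod(Xm, g)) + as.numeric(Pm %*% b)
    if (!all(is.finite(out))) out[] <- 0
    out
  }
  fn_sg <- function(b) {
    s <- state(bm, b, bn, bt)
    ll <- sum(.shash_ll(s$z, s$sigma, s$nu, s$tau))
    if (!is.finite(ll)) return(big)
    -ll + pen(bm, b)
  }
  gr_sg <- function(b) {
    s <- state(bm, b, bn, bt)
    dleta <- -s$z * .shash_dldz(s$z, s$nu, s$tau) - 1
    out <- as.numeric(crossprod(Xs, -dleta)) + as.numeric(Ps %*% b)
    if (!all(is.finite(out))) out[] <- 0
    out
  }
  fn_sh <- function(b) {
    s <- state(bm, bs, b[1], b[2])
    ll <- sum(.shash_ll(s$z, s$sigma, s$nu, s$tau))
    if (!is.finite(ll)) return(big)
    -ll + pen(bm, bs, b[2])
  }
  gr_sh <- function(b) {
    s <- state(bm, bs, b[1], b[2])
    dnu <- sum(.shash_dldnu(s$z, s$nu, s$tau))
    if (spec$nu_link == "log") dnu <- dnu * s$nu
    dlt <- sum(.shash_dldlogtau(s$z, s$nu, s$tau)) - tau_ridge * b[2]
    out <- c(-dnu, -dlt)
    if (!all(is.finite(out))) out[] <- 0
    out
  }

  # two block cycles stabilize the parameter blocks from the deterministic
  # init; a joint quasi-Newton pass then drives the penalized log-likelihood
  # to its optimum (pure block cycling zigzags when blocks are correlated)
  for (cycle in 1:2) {
    bm <- stats::optim(bm, fn_mu, gr_mu, method = "BFGS",
                       control = list(maxit = 60))$par
    bs <- stats::optim(bs, fn_sg, gr_sg, method = "BFGS",
                       control = list(maxit = 60))$par
    if (spec$estimate_shape) {
      o <- stats::optim(c(bn, bt), fn_sh, gr_sh, method = "BFGS",
                        control = list(maxit = 60))
      bn <- o$par[1]; bt <- o$par[2]
    }
  }

  im <- seq_len(pm); is <- pm + seq_len(ps)
  pack <- function() if (spec$estimate_shape) c(bm, bs, bn, bt) else c(bm, bs)
  unpack <- function(th) {
    bm <<- th[im]; bs <<- th[is]
    if (spec$estimate_shape) { bn <<- th[pm + ps + 1]; bt <<- th[pm + ps + 2] }
  }
  fn_all <- function(th) {
    b_m <- th[im]; b_s <- th[is]
    b_n <- if (spec$estimate_shape) th[pm + ps + 1] else bn
    b_t <- if (spec$estimate_shape) th[pm + ps + 2] else bt
    s <- state(b_m, b_s, b_n, b_t)
    ll <- sum(.shash_ll(s$z, s$sigma, s$nu, s$tau))
    if (!is.finite(ll)) return(big)
    -ll + pen(b_m, b_s, if (spec$estimate_shape) b_t else 0)
  }
  gr_all <- function(th) {
    b_m <- th[im]; b_s <- th[is]
    b_n <- if (spec$estimate_shape) th[pm + ps + 1] else bn
    b_t <- if (spec$estimate_shape) th[pm + ps + 2] else bt
    s <- state(b_m, b_s, b_n, b_t)
    dz <- .shash_dldz(s$z, s$nu, s$tau)
    g_m <- as.numeric(crossprod(Xm, dz / s$sigma)) + as.numeric(Pm %*% b_m)
    dleta <- -s$z * dz - 1
    g_s <- as.numeric(crossprod(Xs, -dleta)) + as.numeric(Ps %*% b_s)
    out <- c(g_m, g_s)
    if (spec$estimate_shape) {
      dnu <- sum(.shash_dldnu(s$z, s$nu, s$tau))
      if (spec$nu_link == "log") dnu <- dnu * s$nu
      out <- c(out, -dnu,
               -sum(.shash_dldlogtau(s$z, s$nu, s$tau)) + tau_ridge * b_t)
    }
    if (!all(is.finite(out))) out[] <- 0
    out
  }

  last <- pll(bm, bs, bn, bt)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    prev <- pack()
    o <- stats::optim(prev, fn_all, gr_all, method = "BFGS",
                      control = list(maxit = 400, reltol = 1e-14))
    unpack(o$par)
    cur <- pll(bm, bs, bn, bt)
    trace <- c(trace, cur)
    if (is.finite(cur) && cur - last < tol) {
      if (cur < last) unpack(prev)  # keep the best point seen
      converged <- TRUE
      break
    }
    last <- cur
  }
  if (!converged) {
    cond <- simpleError(sprintf(
      "normative fit did not converge in %d outer iterations", max_outer))
    cond$trace <- trace
    stop(cond)
  }

  s <- state(bm, bs, bn, bt)
  loglik <- sum(.shash_ll(s$z, s$sigma, s$nu, s$tau))

  # effective degrees of freedom from the joint observed information of
  # all parameter blocks (cross-block covariance matters: the sigma
  # smooth and the shape parameters compete for the same moments)
  gu <- function(th) {
    # unpenalized negative log-likelihood gradient
    g <- gr_all(th)
    b_m <- th[im]; b_s <- th[is]
    g[im] <- g[im] - as.numeric(Pm %*% b_m)
    g[is] <- g[is] - as.numeric(Ps %*% b_s)
    g
  }
  th0 <- pack()
  npar <- length(th0)
  H <- matrix(0, npar, npar)
  hstep <- 1e-4 * pmax(abs(th0), 1)
  for (j in seq_len(npar)) {
    tp <- th0; tp[j] <- tp[j] + hstep[j]
    tm <- th0; tm[j] <- tm[j] - hstep[j]
    H[, j] <- (gu(tp) - gu(tm)) / (2 * hstep[j])
  }
  H <- (H + t(H)) / 2
  # clamp numerically negative curvature directions
  eh <- eigen(H, symmetric = TRUE)
  ev <- pmax(eh$values, 1e-8)
  H <- eh$vectors %*% (ev * t(eh$vectors))
  P_all <- matrix(0, npar, npar)
  P_all[im, im] <- Pm
  P_all[is, is] <- Ps
  Fh <- tryCatch(solve(H + P_all + diag(1e-10, npar), H),
                 error = function(e) diag(npar))
  edf1 <- diag(Fh)
  edf2 <- diag(2 * Fh - Fh %*% Fh)
  term_edf <- function(e, terms, off)
    lapply(terms, function(idx) sum(e[idx + off]))
  n_shape <- if (spec$estimate_shape) 2 else 0

  structure(list(
    spec = spec, lambda = lambda,
    coef = list(beta_mu = bm, beta_sigma = bs, beta_nu = bn, beta_tau = bt),
    term_mu = d$term_mu, term_sg = d$term_sg,
    edf_mu = term_edf(edf1, d$term_mu, 0L),
    edf_sg = term_edf(edf1, d$term_sg, pm),
    edf_test_mu = term_edf(edf2, d$term_mu, 0L),
    edf_test_sg = term_edf(edf2, d$term_sg, pm),
    edf_total = sum(edf1),
    loglik = loglik, pen_loglik = last,
    iterations = it, converged = converged, n = length(y)
  ), class = "normative_model")
}

#' Predict SHASH parameters from a fitted normative model
#'
#' @param object a `normative_model`.
#' @param age,sex covariates at which to predict.
#' @param ... unused.
#' @return data.frame with columns `mu`, `sigma`, `nu`, `tau` and a logical
#'   `extrapolated` flag for ages outside the fitted range.
#' @export
predict.normative_model <- function(object, age, sex = NULL, ...) {
  spec <- object$spec
  if (spec$mu_sex && is.null(sex))
    stop("model includes a sex term; supply 'sex'", call. = FALSE)
  if (is.null(sex)) sex <- rep(spec$sex_levels[1] %||% "ref", length(age))
  d <- .nm_designs(spec, age, sex)
  mu <- as.numeric(d$Xm %*% object$coef$beta_mu)
  sigma <- exp(pmin(pmax(as.numeric(d$Xs %*% object$coef$beta_sigma),
                         -30), 30))
  nu <- if (spec$estimate_shape) .nm_nu(object$coef$beta_nu, spec$nu_link)
        else 0
  tau <- if (spec$estimate_shape) exp(object$coef$beta_tau) else 1
  data.frame(mu = mu, sigma = sigma, nu = nu, tau = tau,
             extrapolated = age < spec$age_range[1] |
               age > spec$age_range[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.normative_model <- function(x, ...) {
  cat("SHASH normative model\n")
  cat(sprintf("  n = %d, lambda = %g, edf = %.2f, loglik = %.3f\n",
              x$n, x$lambda, x$edf_total, x$loglik))
  cat(sprintf("  mu: intercept%s%s; log-sigma: intercept%s; nu link: %s\n",
              if (x$spec$mu_age) " + s(age)" else "",
              if (x$spec$mu_sex) " + sex:s(age)" else "",
              if (x$spec$sigma_age) " + s(age)" else "",
              x$spec$nu_link))
  if (isTRUE(x$transfer)) cat("  transferred: intercepts recalibrated\n")
  invisible(x)
}

#' Transfer a normative model to a new cohort by intercept recalibration
#'
#' Re-estimates only the location intercept and the log-scale intercept by
#' maximum likelihood on the new cohort, holding every spline coefficient
#' and the shape parameters fixed. This shifts and rescales the normative
#' distribution to the new sample while preserving the fitted nonlinear
#' age effects.
#'
#' @param model a fitted `normative_model`.
#' @param y_new,age_new,sex_new the new cohort's feature and covariates.
#' @return a new `normative_model` tagged with transfer provenance.
#' @export
transfer_recalibrate <- function(model, y_new, age_new, sex_new = NULL) {
  ok <- is.finite(y_new) & is.finite(age_new)
  y_new <- y_new[ok]; age_new <- age_new[ok]
  if (!is.null(sex_new)) sex_new <- sex_new[ok]
  if (length(y_new) == 0) stop("new cohort is empty", call. = FALSE)
  spec <- model$spec
  if (spec$mu_sex && is.null(sex_new))
    stop("model includes a sex term; supply 'sex_new'", call. = FALSE)
  if (is.null(sex_new))
    sex_new <- rep(spec$sex_levels[1] %||% "ref", length(age_new))
  d <- .nm_designs(spec, age_new, sex_new)
  bm <- model$coef$beta_mu; bs <- model$coef$beta_sigma
  off_mu <- as.numeric(d$Xm[, -1, drop = FALSE] %*% bm[-1])
  off_sg <- as.numeric(d$Xs[, -1, drop = FALSE] %*% bs[-1])
  nu <- if (spec$estimate_shape) .nm_nu(model$coef$beta_nu, spec$nu_link)
        else 0
  tau <- if (spec$estimate_shape) exp(model$coef$beta_tau) else 1
  nll <- function(b) {
    mu <- b[1] + off_mu
    sigma <- exp(pmin(pmax(b[2] + off_sg, -30), 30))
    ll <- sum(.shash_ll((y_new - mu) / sigma, sigma, nu, tau))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  gr <- function(b) {
    mu <- b[1] + off_mu
    sigma <- exp(pmin(pmax(b[2] + off_sg, -30), 30))
    z <- (y_new - mu) / sigma
    dz <- .shash_dldz(z, nu, tau)
    out <- c(sum(dz / sigma), sum(z * dz + 1))
    if (!all(is.finite(out))) out[] <- 0
    out
  }
  # moment-matched start: shift by the mean residual, rescale by the ratio
  # of residual SD to the model's mean scale, then refine by ML
  r0 <- y_new - (bm[1] + off_mu)
  b1_init <- bm[1] + mean(r0)
  sd_model <- mean(exp(pmin(pmax(bs[1] + off_sg, -30), 30)))
  b2_init <- bs[1] + log(max(stats::sd(r0), 1e-8) / sd_model)
  o <- stats::optim(c(b1_init, b2_init), nll, gr, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
  out <- model
  out$coef$beta_mu[1] <- o$par[1]
  out$coef$beta_sigma[1] <- o$par[2]
  out$transfer <- TRUE
  out$transfer_shift <- c(mu = o$par[1] - bm[1], log_sigma = o$par[2] - bs[1])
  out$n <- length(y_new)
  out$loglik <- -o$value
  out
}

#' Centile scores against a normative model
#'
#' Evaluates the fitted SHASH distribution function at each subject's
#' observed value given their age and sex, yielding a score in (0, 1)
#' where 0.5 is the normative median. Subjects outside the fitted age
#' range are scored by constant extrapolation of the parameter curves and
#' flagged with a warning.
#'
#' @param model a `normative_model`, or a list of models (one per feature).
#' @param y numeric vector (one model) or subject-by-feature matrix.
#' @param age,sex subject covariates.
#' @param clip centiles are clipped into `[clip, 1 - clip]`.
#' @return numeric vector or subject-by-feature matrix of centiles.
#' @export
centile_scores <- function(model, y, age, sex = NULL, clip = 1e-6) {
  if (is.list(model) && !inherits(model, "normative_model")) {
    y <- as.matrix(y)
    stopifnot(ncol(y) == length(model))
    out <- vapply(seq_along(model), function(j)
      centile_scores(model[[j]], y[, j], age, sex, clip),
      numeric(nrow(y)))
    out <- matrix(out, nrow = nrow(y))
    dimnames(out) <- dimnames(y)
    return(out)
  }
  p <- predict(model, age, sex)
  if (any(p$extrapolated))
    warning(sprintf("%d subjects outside the fitted age range; scored by extrapolation",
                    sum(p$extrapolated)), call. = FALSE)
  cs <- pshash(y, p$mu, p$sigma, p$nu, p$tau)
  n_clip <- sum(cs < clip | cs > 1 - clip, na.rm = TRUE)
  if (n_clip > 0)
    warning(sprintf("%d centiles clipped to [%g, %g]", n_clip, clip, 1 - clip),
            call. = FALSE)
  pmin(pmax(cs, clip), 1 - clip)
}

#' Normative median curve
#'
#' The 50th percentile of the fitted SHASH distribution on an age grid —
#' the age-specific normative value against which individuals are compared.
#'
#' @param model a `normative_model` or a list of models (one per feature).
#' @param age_grid ages at which to evaluate the median.
#' @param sex a single sex level (recycled) or a vector matching
#'   `age_grid`.
#' @return numeric vector (one model) or grid-by-feature matrix.
#' @export
normative_median_curve <- function(model, age_grid, sex = NULL) {
  if (is.list(model) && !inherits(model, "normative_model")) {
    out <- vapply(model, normative_median_curve, numeric(length(age_grid)),
                  age_grid = age_grid, sex = sex)
    return(matrix(out, nrow = length(age_grid),
                  dimnames = list(NULL, names(model))))
  }
  if (length(sex) == 1) sex <- rep(sex, length(age_grid))
  p <- predict(model, age_grid, sex)
  qshash(0.5, p$mu, p$sigma, p$nu, p$tau)
}

#' Likelihood-ratio test of the age effect on the location
#'
#' Refits the model with an intercept-only location predictor (dropping the
#' age smooth and, when present, the sex-by-age smooth) and compares
#' log-likelihoods. The reference distribution is chi-squared with degrees
#' of freedom equal to the effective degrees of freedom of the dropped
#' smooth terms (the `2F - F^2` form of the effective df, which accounts
#' for penalization of the fit under test).
#'
#' @param model the fitted full model.
#' @param y,age,sex the data the model was fitted on.
#' @return list with `statistic`, `df` and `p`.
#' @export
age_effect_test <- function(model, y, age, sex = NULL) {
  if (!model$spec$mu_age)
    stop("model has no age term on mu; nothing to test", call. = FALSE)
  null <- fit_normative(
    y, age, sex,
    n_knots = model$spec$n_knots, degree = model$spec$degree,
    penalty_order = model$spec$penalty_order, lambda = model$lambda,
    nu_link = model$spec$nu_link, mu_age = FALSE, mu_sex = FALSE,
    sigma_age = model$spec$sigma_age,
    estimate_shape = model$spec$estimate_shape,
    min_n = 2, age_range = model$spec$age_range)
  stat <- max(2 * (model$loglik - null$loglik), 0)
  df <- sum(unlist(model$edf_test_mu[setdiff(names(model$edf_test_mu),
                                             "intercept")]))
  df <- max(df, 1e-8)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Likelihood-ratio test of the age effect on the log-scale
#'
#' Tests whether sigma changes with age by refitting with a constant
#' log-scale and comparing log-likelihoods; the sign of the fitted
#' log-sigma trend (end minus start of the age range) is reported so a
#' narrowing or widening distribution can be distinguished.
#'
#' @inheritParams age_effect_test
#' @return list with `statistic`, `df`, `p` and `trend` (-1/0/+1).
#' @export
sigma_age_test <- function(model, y, age, sex = NULL) {
  if (!model$spec$sigma_age)
    stop("model has no age term on sigma; nothing to test", call. = FALSE)
  null <- fit_normative(
    y, age, sex,
    n_knots = model$spec$n_knots, degree = model$spec$degree,
    penalty_order = model$spec$penalty_order, lambda = model$lambda,
    nu_link = model$spec$nu_link, mu_age = model$spec$mu_age,
    mu_sex = model$spec$mu_sex, sigma_age = FALSE,
    estimate_shape = model$spec$estimate_shape,
    min_n = 2, age_range = model$spec$age_range)
  stat <- max(2 * (model$loglik - null$loglik), 0)
  df <- sum(unlist(model$edf_test_sg[setdiff(names(model$edf_test_sg),
                                             "intercept")]))
  df <- max(df, 1e-8)
  grid <- seq(model$spec$age_range[1], model$spec$age_range[2],
              length.out = 25)
  sg <- predict(model, grid,
                if (model$spec$mu_sex) rep(model$spec$sex_levels[1],
                                           length(grid)) else NULL)$sigma
  trend <- sign(log(sg[length(sg)]) - log(sg[1]))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), trend = trend)
}

#' Fit one normative model per column of a feature matrix
#'
#' @param Y subject-by-feature matrix.
#' @param age,sex subject covariates.
#' @param ... passed to [fit_normative()].
#' @return named list of `normative_model` objects.
#' @export
fit_normative_set <- function(Y, age, sex = NULL, ...) {
  Y <- as.matrix(Y)
  nm <- colnames(Y) %||% paste0("f", seq_len(ncol(Y)))
  out <- lapply(seq_len(ncol(Y)), function(j)
    fit_normative(Y[, j], age, sex, ...))
  names(out) <- nm
  out
}

#' Serialize a normative model to structured text (JSON)
#'
#' Writes the basis specification, coefficient vectors and fit metadata
#' as versioned JSON so models can be stored and transferred between
#' sessions without binary files.
#'
#' @param model a `normative_model`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_normative <- function(model, path) {
  obj <- list(
    format = "gradnorm-normative-model",
    version = 1L,
    spec = model$spec[c("n_knots", "degree", "penalty_order", "nu_link",
                        "mu_age", "mu_sex", "sigma_age", "estimate_shape",
                        "age_range", "sex_levels")],
    knots = model$spec$knots,
    Z = as.numeric(model$spec$Z),
    Z_dim = dim(model$spec$Z),
    coef = model$coef,
    lambda = model$lambda,
    loglik = model$loglik,
    edf_total = model$edf_total,
    n = model$n,
    transfer = isTRUE(model$transfer)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a serialized normative model
#'
#' @param path file written by [write_normative()].
#' @return a `normative_model` usable for prediction, scoring and
#'   transfer.
#' @export
read_normative <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gradnorm-normative-model"))
    stop("not a serialized normative model", call. = FALSE)
  spec <- as.list(obj$spec)
  if (length(spec$sex_levels) == 0) spec$sex_levels <- NULL
  spec$knots <- as.numeric(obj$knots)
  spec$Z <- matrix(as.numeric(obj$Z), obj$Z_dim[1], obj$Z_dim[2])
  structure(list(
    spec = spec,
    coef = lapply(obj$coef, as.numeric),
    lambda = obj$lambda, loglik = obj$loglik,
    edf_total = obj$edf_total, n = obj$n, transfer = obj$transfer
  ), class = "normative_model")
}
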