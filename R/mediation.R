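#' Single-mediator bootstrap mediation analysis
#'
#' Decomposes the effect of a binary exposure `x` (e.g. diagnostic group)
#' on an outcome `y` (e.g. hierarchy score) into the path through a
#' mediator `m` (e.g. a PC centile): `a` (x to m), `b` (m to y given x),
#' direct effect `c'`, total effect `c = c' + a*b`, and indirect effect
#' `a*b`. All paths are standardized regression weights. Inference uses a
#' percentile bootstrap over subjects: rows are resampled with
#' replacement, every path is refit and standardized within each
#' resample, the CI is the 2.5/97.5 percentile interval of the bootstrap
#' indirect effects, and the two-sided p-value is twice the smaller tail
#' proportion of bootstrap indirect effects crossing zero. Resamples in
#' which `x` has a single level (or a variable is constant) are redrawn
#' and counted.
#'
#' @param x exposure: numeric, factor or logical with exactly two levels.
#' @param m,y mediator and outcome, numeric.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @return object of class `mediation_result`: list with `paths`
#'   (a, b, c, c_prime, indirect), `ci`, `p`, `n`, `n_boot`, `n_redrawn`,
#'   `seed`.
#' @export
mediate <- function(x, m, y, n_boot = 5000, seed = 1L, conf = 0.95) {
  if (is.factor(x) || is.character(x) || is.logical(x))
    x <- as.numeric(factor(x)) - 1
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  n <- length(x)
  if (length(m) != n || length(y) != n)
    stop("x, m, y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(m) & is.finite(y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]; n <- length(x)
  if (n < 10) stop("need at least 10 complete observations", call. = FALSE)
  if (length(unique(x)) != 2)
    stop("'x' must have exactly two levels", call. = FALSE)
  if (stats::sd(m) == 0 || stats::sd(y) == 0)
    stop("constant mediator or outcome", call. = FALSE)

  paths_from_moments <- function(mx, mm, my, sxx, smm, syy, sxm, sxy, smy) {
    # raw OLS coefficients, then standardized by the sample SDs
    a <- sxm / sxx
    det <- sxx * smm - sxm^2
    cp <- (smm * sxy - sxm * smy) / det
    b <- (sxx * smy - sxm * sxy) / det
    ctot <- sxy / sxx
    sx <- sqrt(sxx); sm <- sqrt(smm); sy <- sqrt(syy)
    c(a = a * sx / sm, b = b * sm / sy, c = ctot * sx / sy,
      c_prime = cp * sx / sy, indirect = (a * sx / sm) * (b * sm / sy))
  }
  moments <- function(xs, ms, ys) {
    mx <- mean(xs); mm <- mean(ms); my <- mean(ys)
    paths_from_moments(mx, mm, my,
                       mean(xs^2) - mx^2, mean(ms^2) - mm^2,
                       mean(ys^2) - my^2, mean(xs * ms) - mx * mm,
                       mean(xs * ys) - mx * my, mean(ms * ys) - mm * my)
  }
  est <- moments(x, m, y)

  # vectorized bootstrap: one index matrix, moment sums by column
  boot_paths <- function(idx) {
    X <- matrix(x[idx], n); M <- matrix(m[idx], n); Y <- matrix(y[idx], n)
    mx <- colMeans(X); mm <- colMeans(M); my <- colMeans(Y)
    sxx <- colMeans(X^2) - mx^2; smm <- colMeans(M^2) - mm^2
    syy <- colMeans(Y^2) - my^2
    sxm <- colMeans(X * M) - mx * mm; sxy <- colMeans(X * Y) - mx * my
    smy <- colMeans(M * Y) - mm * my
    bad <- sxx <= 0 | smm <= 0 | syy <= 0
    a <- sxm / sxx
    det <- sxx * smm - sxm^2
    b <- (sxx * smy - sxm * sxy) / det
    ind <- (a * sqrt(sxx) / sqrt(smm)) * (b * sqrt(smm) / sqrt(syy))
    list(ind = ind, bad = bad)
  }
  n_redrawn <- 0L
  ind_b <- .with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n)
    bp <- boot_paths(idx)
    while (any(bp$bad)) {
      nb <- sum(bp$bad)
      n_redrawn <- n_redrawn + nb
      idx2 <- matrix(sample.int(n, n * nb, replace = TRUE), n)
      bp2 <- boot_paths(idx2)
      bp$ind[bp$bad] <- bp2$ind
      bp$bad[bp$bad] <- bp2$bad
    }
    bp$ind
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(ind_b, c(alpha, 1 - alpha), names = FALSE)
  p <- min(2 * min(mean(ind_b < 0), mean(ind_b > 0)), 1)
  structure(list(paths = est, ci = ci, p = p, n = n, n_boot = n_boot,
                 n_redrawn = n_redrawn, conf = conf, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Bootstrap mediation (standardized paths)\n")
  cat(sprintf("  a = %.3f, b = %.3f, c = %.3f, c' = %.3f\n",
              x$paths["a"], x$paths["b"], x$paths["c"], x$paths["c_prime"]))
  cat(sprintf("  indirect = %.3f, %.0f%% CI [%.3f, %.3f], p = %.4f (%d boots, n = %d)\n",
              x$paths["indirect"], 100 * x$conf, x$ci[1], x$ci[2], x$p,
              x$n_boot, x$n))
  invisible(x)
}

#' Mediation of group differences by PC centiles, per developmental stage
#'
#' Runs [mediate()] with the diagnostic group as exposure and the
#' hierarchy score as outcome, for each PC-centile mediator (whole-brain
#' and each network), within each age bin and pooled over all ages.
#' Within each bin the network mediators' p-values are BH-adjusted
#' (the whole-brain summary, an aggregate of the networks, is reported
#' unadjusted).
#'
#' @param pc_cent subject-by-feature matrix of PC centiles (cohort order;
#'   typically the `"reference"` convention of [pc_centiles()]).
#' @param scores numeric vector of hierarchy scores (cohort order).
#' @param cohort cohort table with age and group.
#' @param breaks age-bin boundaries.
#' @param n_boot,seed bootstrap parameters.
#' @param min_cell minimum per-group size within a bin.
#' @return data.frame with bin, mediator, n, a, b, c, c_prime, indirect,
#'   ci_lo, ci_hi, p, q. Empty bin-group cells are skipped with an `NA`
#'   row.
#' @export
mediation_by_stage <- function(pc_cent, scores, cohort,
                               breaks = c(5, 12, 15, 22),
                               n_boot = 5000, seed = 1L, min_cell = 10) {
  pc_cent <- as.matrix(pc_cent)
  stopifnot(nrow(pc_cent) == nrow(cohort), length(scores) == nrow(cohort))
  bins <- assign_age_bin(cohort$age, breaks)
  stages <- c(levels(bins), "all")
  feats <- colnames(pc_cent) %||% paste0("f", seq_len(ncol(pc_cent)))
  rows <- list()
  si <- 0L
  for (b in stages) {
    idx <- if (b == "all") seq_len(nrow(cohort)) else which(bins == b)
    grp <- as.character(cohort$group[idx])
    enough <- length(unique(grp)) == 2 && min(table(grp)) >= min_cell
    for (j in seq_along(feats)) {
      si <- si + 1L
      m_ok <- enough && sum(is.finite(pc_cent[idx, j])) >= 2 * min_cell &&
        stats::sd(pc_cent[idx, j], na.rm = TRUE) > 0
      if (!m_ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          bin = b, mediator = feats[j], n = length(idx), a = NA_real_,
          b_path = NA_real_, c = NA_real_, c_prime = NA_real_,
          indirect = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          p = NA_real_)
        next
      }
      # explicit exposure coding (reference group 0, clinical group 1)
      # so results do not depend on factor-level ordering
      xg <- as.character(cohort$group[idx])
      x_num <- if (all(xg %in% c("TD", "ASD"))) as.numeric(xg == "ASD")
               else cohort$group[idx]
      mr <- mediate(x_num, pc_cent[idx, j], scores[idx],
                    n_boot = n_boot, seed = seed + si)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, mediator = feats[j], n = mr$n, a = mr$paths["a"],
        b_path = mr$paths["b"], c = mr$paths["c"],
        c_prime = mr$paths["c_prime"], indirect = mr$paths["indirect"],
        ci_lo = mr$ci[1], ci_hi = mr$ci[2], p = mr$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  for (b in stages) {
    net <- out$bin == b & out$mediator != "WholeBrain"
    out$q[net] <- stats::p.adjust(out$p[net], "BH")
  }
  out
}
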