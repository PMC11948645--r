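#' Whole-brain hierarchy score
#'
#' Cosine similarity between an individual's principal gradient and the
#' age/sex-specific normative gradient:
#' `score = (norm_g1 . g1) / (||norm_g1|| ||g1||)`.
#' 1 means the individual's cortical hierarchy matches the normative
#' pattern exactly; 0 orthogonal; -1 reversed. Scale-invariant in both
#' arguments.
#'
#' @param g1 individual gradient, length P.
#' @param norm_g1 normative gradient at the individual's age/sex, length P.
#' @return scalar in \[-1, 1\].
#' @export
hierarchy_score <- function(g1, norm_g1) {
  if (length(g1) != length(norm_g1))
    stop("gradient vectors differ in length", call. = FALSE)
  n1 <- sqrt(sum(g1^2)); n2 <- sqrt(sum(norm_g1^2))
  if (n1 == 0 || n2 == 0)
    stop("hierarchy score undefined for a zero gradient", call. = FALSE)
  sum(g1 * norm_g1) / (n1 * n2)
}

#' Hierarchy scores for a cohort
#'
#' For each subject, evaluates the per-parcel normative median gradient at
#' the subject's age and sex and computes the cosine similarity with the
#' subject's aligned principal gradient.
#'
#' @param g1_matrix subject-by-parcel matrix of aligned first-gradient
#'   values (rows in cohort order).
#' @param models list of per-parcel `normative_model`s (length P).
#' @param cohort cohort table with `age` (and `sex` if the models use it).
#' @return data.frame with subject_id (if present), age, group (if
#'   present) and `score`.
#' @export
score_cohort <- function(g1_matrix, models, cohort) {
  g1_matrix <- as.matrix(g1_matrix)
  if (ncol(g1_matrix) != length(models))
    stop("number of models must equal number of parcels", call. = FALSE)
  if (nrow(g1_matrix) != nrow(cohort))
    stop("gradient matrix and cohort sizes differ", call. = FALSE)
  sex <- cohort$sex
  # normative median for every parcel at every subject's age/sex
  norm_mat <- vapply(models, function(m) {
    p <- predict(m, cohort$age, sex)
    qshash(0.5, p$mu, p$sigma, p$nu, p$tau)
  }, numeric(nrow(cohort)))
  norm_mat <- matrix(norm_mat, nrow = nrow(cohort))
  score <- vapply(seq_len(nrow(cohort)), function(i)
    hierarchy_score(g1_matrix[i, ], norm_mat[i, ]), numeric(1))
  out <- data.frame(score = score)
  for (col in c("subject_id", "age", "sex", "group"))
    if (!is.null(cohort[[col]])) out[[col]] <- cohort[[col]]
  out[, c(setdiff(names(out), "score"), "score")]
}

#' Group-wise hierarchy-score trajectory
#'
#' Fits the SHASH normative model to one group's hierarchy scores as a
#' function of age (and sex), and summarizes the fitted median curve:
#' 2.5/50/97.5 centile bands on an age grid, a per-sex slope (the mean
#' derivative of the median curve over the fitted range), and the peak
#' age when the curve has an interior maximum at least `peak_margin`
#' years away from the range boundaries.
#'
#' @param scores data.frame from [score_cohort()] (needs score, age, and
#'   optionally sex/group).
#' @param group group label to fit (`NULL` = use all rows).
#' @param age_grid evaluation grid; defaults to 200 points over the
#'   fitted range.
#' @param peak_margin minimum distance (years) of a reported peak from
#'   the range boundary.
#' @param ... passed to [fit_normative()].
#' @return object of class `trajectory_fit` with elements `model`,
#'   `curves` (long data.frame: sex, age, lo, median, hi), `slopes`
#'   (per sex), `peak_age` (per sex, `NA` when the curve is monotone or
#'   the maximum is at the edge).
#' @export
fit_score_trajectory <- function(scores, group = NULL, age_grid = NULL,
                                 peak_margin = 0.5, ...) {
  df <- scores
  if (!is.null(group)) {
    if (is.null(df$group)) stop("scores carry no group column", call. = FALSE)
    df <- df[as.character(df$group) == group, ]
    if (nrow(df) == 0) stop("group '", group, "' not present", call. = FALSE)
  }
  model <- fit_normative(df$score, df$age, df$sex, ...)
  rng <- model$spec$age_range
  if (is.null(age_grid)) age_grid <- seq(rng[1], rng[2], length.out = 200)
  sexes <- if (isTRUE(model$spec$mu_sex)) model$spec$sex_levels
           else "all"
  curves <- do.call(rbind, lapply(sexes, function(sx) {
    p <- predict(model, age_grid,
                 if (sx == "all" && is.null(model$spec$sex_levels)) NULL
                 else rep(if (sx == "all") model$spec$sex_levels[1] %||% "ref"
                          else sx, length(age_grid)))
    data.frame(sex = sx, age = age_grid,
               lo = qshash(0.025, p$mu, p$sigma, p$nu, p$tau),
               median = qshash(0.5, p$mu, p$sigma, p$nu, p$tau),
               hi = qshash(0.975, p$mu, p$sigma, p$nu, p$tau))
  }))
  slope_peak <- lapply(sexes, function(sx) {
    med <- curves$median[curves$sex == sx]
    dd <- diff(med) / diff(age_grid)
    slope <- mean(dd)
    imax <- which.max(med)
    interior <- age_grid[imax] - rng[1] >= peak_margin &&
      rng[2] - age_grid[imax] >= peak_margin
    monotone <- all(dd >= -1e-12) || all(dd <= 1e-12)
    list(slope = slope,
         peak = if (interior && !monotone) age_grid[imax] else NA_real_)
  })
  structure(list(
    group = group %||% "all", model = model, curves = curves,
    slopes = stats::setNames(vapply(slope_peak, `[[`, 1, "slope"), sexes),
    peak_age = stats::setNames(vapply(slope_peak, `[[`, 1, "peak"), sexes),
    pointwise_slope = stats::setNames(
      lapply(sexes, function(sx) {
        med <- curves$median[curves$sex == sx]
        data.frame(age = age_grid[-1] - diff(age_grid) / 2,
                   slope = diff(med) / diff(age_grid))
      }), sexes),
    n = nrow(df)
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory_fit (%s, n = %d)\n", x$group, x$n))
  for (sx in names(x$slopes))
    cat(sprintf("  %s: slope %.4f/year, peak age %s\n", sx, x$slopes[sx],
                if (is.na(x$peak_age[sx])) "none (monotone)"
                else sprintf("%.2f y", x$peak_age[sx])))
  invisible(x)
}

#' Age trend of the score variance (sigma) in one group
#'
#' Fits the group's hierarchy-score normative model and tests the age
#' smooth on log-sigma by likelihood ratio, returning the trend sign
#' (negative = narrowing with age, i.e. convergence to the norm).
#'
#' The default smoothing weight is deliberately strong: a second-order
#' difference penalty leaves linear log-sigma trends unpenalized, so
#' heavy smoothing reduces the scale smooth to a near-linear trend model
#' whose chi-squared reference is well calibrated, with no power loss
#' against monotone variance trends.
#'
#' @inheritParams fit_score_trajectory
#' @param lambda smoothing weight for the internal fit.
#' @return list with `statistic`, `df`, `p`, `trend` and the fitted model.
#' @export
sigma_age_effect <- function(scores, group = NULL, lambda = 1000, ...) {
  df <- scores
  if (!is.null(group)) {
    df <- df[as.character(df$group) == group, ]
    if (nrow(df) == 0) stop("group '", group, "' not present", call. = FALSE)
  }
  model <- fit_normative(df$score, df$age, df$sex, lambda = lambda, ...)
  out <- sigma_age_test(model, df$score, df$age, df$sex)
  out$model <- model
  out
}

# vectorized Welch two-sample t-test per column
.welch_cols <- function(A, B) {
  nA <- colSums(!is.na(A)); nB <- colSums(!is.na(B))
  mA <- colMeans(A, na.rm = TRUE); mB <- colMeans(B, na.rm = TRUE)
  vA <- apply(A, 2, stats::var, na.rm = TRUE)
  vB <- apply(B, 2, stats::var, na.rm = TRUE)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(t = t, df = df, p = p)
}

#' Compare centile scores between groups
#'
#' Welch (unequal-variance) two-sample t-test per feature, ASD minus TD,
#' with Benjamini-Hochberg adjustment across features. Identical groups
#' give t = 0 and q = 1.
#'
#' @param centiles_asd,centiles_td subject-by-feature centile matrices.
#' @return data.frame with feature, t, df, p, q (BH-adjusted).
#' @export
compare_centiles <- function(centiles_asd, centiles_td) {
  A <- as.matrix(centiles_asd); B <- as.matrix(centiles_td)
  if (ncol(A) != ncol(B)) stop("feature counts differ", call. = FALSE)
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  res <- .welch_cols(A, B)
  res$t[is.nan(res$t)] <- 0
  res$p[is.nan(res$p) | is.na(res$p)] <- 1
  data.frame(feature = colnames(A) %||% paste0("f", seq_len(ncol(A))),
             t = res$t, df = res$df, p = res$p,
             q = stats::p.adjust(res$p, "BH"), row.names = NULL)
}

#' Average centiles within canonical networks
#'
#' @param centiles subject-by-parcel centile matrix.
#' @param atlas `parcel_atlas` matching the parcel columns.
#' @return subject-by-network matrix (7 columns, Yeo-7 order).
#' @export
network_average_centiles <- function(centiles, atlas) {
  centiles <- as.matrix(centiles)
  if (ncol(centiles) != atlas$P)
    stop("centile columns do not match the atlas", call. = FALSE)
  out <- vapply(levels(atlas$network_of), function(nw)
    rowMeans(centiles[, atlas$network_of == nw, drop = FALSE]),
    numeric(nrow(centiles)))
  matrix(out, nrow = nrow(centiles),
         dimnames = list(rownames(centiles), levels(atlas$network_of)))
}

#' Assign developmental-stage age bins
#'
#' Half-open bins `[lo, hi)`; the final bin includes its upper boundary.
#' With the default breaks, age 12 falls in the second bin and 15 in the
#' third.
#'
#' @param age numeric vector.
#' @param breaks bin boundaries (default 5, 12, 15, 22).
#' @return factor with levels like `"5-12"`, `"12-15"`, `"15-22"`.
#' @export
assign_age_bin <- function(age, breaks = c(5, 12, 15, 22)) {
  labs <- paste(utils::head(breaks, -1), breaks[-1], sep = "-")
  cut(age, breaks, labels = labs, right = FALSE, include.lowest = TRUE)
}

#' Network-level group comparison within developmental stages
#'
#' Within each age bin, averages parcel centiles into the 7 canonical
#' networks per subject and compares ASD vs TD with Welch t-tests,
#' FDR-corrected across networks within the bin.
#'
#' @param centiles subject-by-parcel centile matrix (cohort order).
#' @param cohort cohort table with age and group.
#' @param atlas `parcel_atlas`.
#' @param breaks age-bin boundaries.
#' @return data.frame with bin, feature (network), n_td, n_asd, t, p, q;
#'   bins with an empty group cell are flagged with `NA` statistics.
#' @export
age_bin_analysis <- function(centiles, cohort, atlas,
                             breaks = c(5, 12, 15, 22)) {
  net <- network_average_centiles(centiles, atlas)
  bins <- assign_age_bin(cohort$age, breaks)
  grp <- as.character(cohort$group)
  out <- list()
  for (b in levels(bins)) {
    ia <- which(bins == b & grp == "ASD")
    it <- which(bins == b & grp == "TD")
    if (length(ia) < 2 || length(it) < 2) {
      out[[b]] <- data.frame(bin = b, feature = colnames(net),
                             n_td = length(it), n_asd = length(ia),
                             t = NA_real_, p = NA_real_, q = NA_real_)
      next
    }
    cc <- compare_centiles(net[ia, , drop = FALSE], net[it, , drop = FALSE])
    out[[b]] <- data.frame(bin = b, feature = cc$feature,
                           n_td = length(it), n_asd = length(ia),
                           t = cc$t, p = cc$p, q = cc$q)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation of hierarchy scores with symptom scales
#'
#' Pearson correlation of the score with each symptom column, BH-adjusted
#' across scales.
#'
#' @param scores numeric vector of hierarchy scores.
#' @param symptoms data.frame/matrix of symptom scales (e.g. srs_total
#'   and subscores), rows matching `scores`.
#' @return data.frame with scale, n, r, p, q.
#' @export
behavior_correlation <- function(scores, symptoms) {
  symptoms <- as.data.frame(symptoms)
  if (nrow(symptoms) != length(scores))
    stop("scores and symptoms differ in length", call. = FALSE)
  res <- lapply(names(symptoms), function(sc) {
    v <- symptoms[[sc]]
    ok <- is.finite(v) & is.finite(scores)
    if (sum(ok) < 3)
      stop("fewer than 3 paired observations for scale ", sc, call. = FALSE)
    if (stats::sd(v[ok]) == 0)
      stop("symptom scale '", sc, "' is constant", call. = FALSE)
    ct <- stats::cor.test(scores[ok], v[ok])
    data.frame(scale = sc, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, "BH")
  res
}
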