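#' Participation coefficient of a binary graph over network modules
#'
#' For node `i` with total degree `k_i` and degree `k_i(m)` into module
#' `m`, `PC_i = 1 - sum_m (k_i(m) / k_i)^2`. 0 means all edges stay in
#' one module (fully segregated); the maximum `1 - 1/|M|` (6/7 for seven
#' modules) means edges spread evenly over all modules. Degree-0 nodes
#' get PC 0 with a warning.
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @param atlas `parcel_atlas` supplying the module partition (must cover
#'   all nodes).
#' @return list of class `pc_vector`: `pc` (per parcel), `whole_brain`
#'   (mean PC), `per_network` (named mean PC within each network).
#' @export
participation_coefficient <- function(adj, atlas) {
  A <- as.matrix(adj)
  P <- nrow(A)
  if (atlas$P != P)
    stop(sprintf("partition covers %d parcels but graph has %d nodes",
                 atlas$P, P), call. = FALSE)
  if (max(abs(A - t(A))) > 0) stop("adjacency must be symmetric",
                                   call. = FALSE)
  if (!all(A %in% c(0, 1))) stop("adjacency must be 0/1", call. = FALSE)
  k <- rowSums(A)
  km <- vapply(levels(atlas$network_of), function(nw)
    rowSums(A[, atlas$network_of == nw, drop = FALSE]), numeric(P))
  pc <- 1 - rowSums((km / pmax(k, 1))^2)
  iso <- k == 0
  if (any(iso)) {
    warning(sprintf("%d isolated node(s); PC set to 0", sum(iso)),
            call. = FALSE)
    pc[iso] <- 0
  }
  per_net <- vapply(levels(atlas$network_of), function(nw)
    mean(pc[atlas$network_of == nw]), numeric(1))
  structure(list(pc = stats::setNames(pc, atlas$parcel_id),
                 whole_brain = mean(pc), per_network = per_net),
            class = "pc_vector")
}

#' Participation-coefficient summary table for a cohort
#'
#' Binarizes each subject's connectivity to the top-density positive
#' graph, computes the participation coefficient, and returns the
#' whole-brain mean plus the 7 network means as features.
#'
#' @param fc_list list of P-by-P Fisher-z matrices (cohort order).
#' @param atlas `parcel_atlas`.
#' @param density binarization density.
#' @return subject-by-feature matrix with columns `WholeBrain` and the 7
#'   network names.
#' @export
pc_summary_table <- function(fc_list, atlas, density = 0.10) {
  out <- t(vapply(fc_list, function(W) {
    pcv <- participation_coefficient(binarize_positive_top(W, density),
                                     atlas)
    c(WholeBrain = pcv$whole_brain, pcv$per_network)
  }, numeric(1 + nlevels(atlas$network_of))))
  rownames(out) <- names(fc_list)
  out
}

#' Normative centile scores for PC summaries
#'
#' Fits SHASH normative age models to each PC summary (whole-brain and
#' the 7 networks) and scores subjects as centiles. Two referencing
#' conventions are supported: `"within"` fits each group separately and
#' scores its members against their own group's model (controls for age,
#' sex and diagnosis simultaneously); `"reference"` fits on the reference
#' group only and scores everyone against it, preserving group contrasts
#' (the convention needed when PC centiles enter group-mediation models).
#'
#' @param pc_table subject-by-feature PC matrix (cohort order).
#' @param cohort cohort table with age, sex, group.
#' @param reference `"within"` or `"reference"`.
#' @param reference_group group used when `reference = "reference"`.
#' @param ... passed to [fit_normative()].
#' @return list with `centiles` (subject-by-feature matrix) and `models`
#'   (per group or for the reference group).
#' @export
pc_centiles <- function(pc_table, cohort,
                        reference = c("within", "reference"),
                        reference_group = "TD", ...) {
  reference <- match.arg(reference)
  pc_table <- as.matrix(pc_table)
  stopifnot(nrow(pc_table) == nrow(cohort))
  cent <- matrix(NA_real_, nrow(pc_table), ncol(pc_table),
                 dimnames = dimnames(pc_table))
  # constant PC summaries (possible in tiny or highly deterministic
  # graphs) carry no normative information: flagged and left NA
  fit_cols <- function(idx) {
    ok <- apply(pc_table[idx, , drop = FALSE], 2, stats::sd) > 0
    if (any(!ok))
      warning("constant PC summaries skipped: ",
              paste(colnames(pc_table)[!ok], collapse = ", "),
              call. = FALSE)
    ok
  }
  if (reference == "within") {
    models <- list()
    for (g in unique(as.character(cohort$group))) {
      idx <- which(as.character(cohort$group) == g)
      ok <- fit_cols(idx)
      models[[g]] <- fit_normative_set(pc_table[idx, ok, drop = FALSE],
                                       cohort$age[idx], cohort$sex[idx], ...)
      cent[idx, ok] <- centile_scores(models[[g]],
                                      pc_table[idx, ok, drop = FALSE],
                                      cohort$age[idx], cohort$sex[idx])
    }
  } else {
    idx <- which(as.character(cohort$group) == reference_group)
    if (length(idx) == 0)
      stop("reference group '", reference_group, "' not present",
           call. = FALSE)
    ok <- fit_cols(idx)
    models <- fit_normative_set(pc_table[idx, ok, drop = FALSE],
                                cohort$age[idx], cohort$sex[idx], ...)
    cent[, ok] <- centile_scores(models, pc_table[, ok, drop = FALSE],
                                 cohort$age, cohort$sex)
  }
  list(centiles = cent, models = models, reference = reference)
}

#' Age trend of PC summaries
#'
#' Fits a normative model per PC summary within one group and tests the
#' age effect on the location by likelihood ratio, BH-adjusted across the
#' 8 summaries. The trend sign is the sign of the fitted median change
#' over the age range.
#'
#' @param pc_table subject-by-feature PC matrix (cohort order).
#' @param cohort cohort table.
#' @param group group to analyze (default TD).
#' @param ... passed to [fit_normative()].
#' @return data.frame with feature, statistic, df, p, q, trend.
#' @export
pc_age_trend <- function(pc_table, cohort, group = "TD", ...) {
  idx <- which(as.character(cohort$group) == group)
  if (length(idx) == 0) stop("group not present", call. = FALSE)
  pc_table <- as.matrix(pc_table)
  age <- cohort$age[idx]; sex <- cohort$sex[idx]
  res <- lapply(colnames(pc_table) %||% paste0("f", seq_len(ncol(pc_table))),
                function(ft) ft)
  out <- do.call(rbind, lapply(seq_len(ncol(pc_table)), function(j) {
    y <- pc_table[idx, j]
    if (stats::sd(y) == 0)
      return(data.frame(feature = res[[j]], statistic = NA_real_,
                        df = NA_real_, p = NA_real_, trend = NA_real_))
    m <- fit_normative(y, age, sex, ...)
    tst <- age_effect_test(m, y, age, sex)
    grid <- seq(m$spec$age_range[1], m$spec$age_range[2], length.out = 25)
    med <- normative_median_curve(
      m, grid, if (m$spec$mu_sex) m$spec$sex_levels[1] else NULL)
    data.frame(feature = res[[j]], statistic = tst$statistic, df = tst$df,
               p = tst$p, trend = sign(med[length(med)] - med[1]))
  }))
  out$q <- stats::p.adjust(out$p, "BH")
  out[, c("feature", "statistic", "df", "p", "q", "trend")]
}
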