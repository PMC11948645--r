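# End-to-end orchestration over the synthetic cohort: simulate ->
# connectome -> gradients/template/alignment -> per-parcel normative
# models on the reference group -> centiles -> hierarchy scores ->
# group trajectories -> participation coefficients -> PC centiles ->
# mediation. Each stage only consumes the previous stage's declared
# outputs, and every table can be written to a run directory.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]. The
#' reference conventions mirror a normative study design: the gradient
#' template and the per-parcel normative models are fit on the TD group
#' and everyone is scored against them, while PC centiles are computed
#' both within-group and TD-referenced (the latter feed the mediation
#' models).
#'
#' @param P parcel count.
#' @param n_td,n_asd group sizes.
#' @param k number of gradient components.
#' @param density row-threshold density for gradients (also used for the
#'   binary topology graph).
#' @param lambda smoothing weight for the per-parcel normative fits
#'   (fixed rather than grid-searched; one value for the whole parcel
#'   loop).
#' @param n_boot mediation bootstrap count.
#' @param breaks age-bin boundaries.
#' @param seed base seed for the generator and bootstrap.
#' @param rho_symptoms target correlation of symptom scores with the
#'   planted alignment (set to `NULL` to skip symptom simulation).
#' @param truth_args extra arguments for [sim_truth()].
#' @return named list.
#' @export
pipeline_config <- function(P = 200, n_td = 300, n_asd = 300, k = 5,
                            density = 0.10, lambda = 10, n_boot = 5000,
                            breaks = c(5, 12, 15, 22), seed = 1L,
                            rho_symptoms = -0.3, truth_args = list()) {
  cfg <- list(P = P, n_td = n_td, n_asd = n_asd, k = k, density = density,
              lambda = lambda, n_boot = n_boot, breaks = breaks,
              seed = as.integer(seed), rho_symptoms = rho_symptoms,
              truth_args = truth_args)
  if (density <= 0 || density >= 1)
    stop("'density' must lie in (0, 1)", call. = FALSE)
  cfg
}

#' Run the full gradient-normative analysis on a synthetic cohort
#'
#' @param config list from [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs are
#'   written as CSV/TSV plus a JSON manifest with the config hash.
#' @param verbose print stage progress.
#' @return list with cohort, truth tables, gradient matrix, centiles,
#'   hierarchy scores, trajectories, sigma tests, age-bin tables, PC
#'   tables and mediation results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("[1/6] simulating cohort (P = %d, %d TD + %d ASD)",
      config$P, config$n_td, config$n_asd)
  atlas <- make_atlas(config$P)
  truth <- do.call(sim_truth,
                   c(list(atlas = atlas, seed = config$seed),
                     config$truth_args))
  cohort <- simulate_cohort(config$n_td, config$n_asd, truth)
  sim <- simulate_cohort_connectivity(cohort, truth, atlas)
  if (!is.null(config$rho_symptoms))
    cohort <- simulate_symptoms(cohort, sim$truth_table$alignment,
                                config$rho_symptoms,
                                seed = config$seed + 11L)

  say("[2/6] gradients: embedding %d subjects, aligning to TD template",
      nrow(cohort))
  td_idx <- which(cohort$group == "TD")
  template <- build_template(sim$matrices[td_idx], k = config$k,
                             density = config$density, atlas = atlas)
  G1 <- t(vapply(sim$matrices, function(W) {
    g <- diffusion_embedding(
      normalized_angle_affinity(row_threshold(W, config$density)),
      k = config$k)
    procrustes_align(g, template)$components[, 1]
  }, numeric(config$P)))

  say("[3/6] normative models: %d parcels on %d TD subjects",
      config$P, length(td_idx))
  min_n <- min(50L, length(td_idx))
  models <- fit_normative_set(G1[td_idx, , drop = FALSE],
                              cohort$age[td_idx], cohort$sex[td_idx],
                              lambda = config$lambda, min_n = min_n)
  centiles <- suppressWarnings(
    centile_scores(models, G1, cohort$age, cohort$sex))
  colnames(centiles) <- atlas$parcel_id
  age_tests <- do.call(rbind, lapply(seq_along(models), function(j) {
    tst <- age_effect_test(models[[j]], G1[td_idx, j],
                           cohort$age[td_idx], cohort$sex[td_idx])
    data.frame(parcel_id = atlas$parcel_id[j], statistic = tst$statistic,
               df = tst$df, p = tst$p)
  }))
  age_tests$q <- stats::p.adjust(age_tests$p, "BH")

  say("[4/6] hierarchy scores and group trajectories")
  scores <- score_cohort(G1, models, cohort)
  traj <- lapply(c(TD = "TD", ASD = "ASD"), function(g)
    fit_score_trajectory(scores, group = g, lambda = config$lambda,
                         min_n = min_n))
  # sex-pooled ASD trajectory: the stable group-level peak estimate
  traj$ASD_pooled <- fit_score_trajectory(scores, group = "ASD",
                                          lambda = config$lambda,
                                          mu_sex = FALSE, min_n = min_n)
  sigma_tests <- lapply(c(TD = "TD", ASD = "ASD"), function(g)
    sigma_age_effect(scores, group = g, min_n = min_n))
  bin_table <- age_bin_analysis(centiles, cohort, atlas,
                                breaks = config$breaks)
  behavior <- NULL
  if (!is.null(config$rho_symptoms)) {
    asd <- cohort$group == "ASD"
    behavior <- behavior_correlation(
      scores$score[asd],
      cohort[asd, grep("^srs_", names(cohort)), drop = FALSE])
  }

  say("[5/6] topology: participation coefficients and PC centiles")
  pc_tab <- suppressWarnings(
    pc_summary_table(sim$matrices, atlas, density = config$density))
  pc_within <- suppressWarnings(
    pc_centiles(pc_tab, cohort, reference = "within",
                lambda = config$lambda, min_n = min_n))
  pc_ref <- suppressWarnings(
    pc_centiles(pc_tab, cohort, reference = "reference",
                reference_group = "TD", lambda = config$lambda,
                min_n = min_n))
  pc_trend <- pc_age_trend(pc_tab, cohort, group = "TD",
                           lambda = config$lambda, min_n = min_n)

  say("[6/6] mediation: group -> PC centile -> hierarchy score")
  mediation <- mediation_by_stage(pc_ref$centiles, scores$score, cohort,
                                  breaks = config$breaks,
                                  n_boot = config$n_boot,
                                  seed = config$seed + 77L)

  res <- list(config = config, atlas = atlas, truth = truth,
              cohort = cohort, truth_table = sim$truth_table,
              template = template, G1 = G1, models = models,
              centiles = centiles, age_tests = age_tests, scores = scores,
              trajectories = traj, sigma_tests = sigma_tests,
              bin_table = bin_table, behavior = behavior,
              pc_table = pc_tab, pc_within = pc_within$centiles,
              pc_ref = pc_ref$centiles, pc_trend = pc_trend,
              mediation = mediation,
              elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) write_run(res, out_dir)
  say("pipeline finished in %.1f s", res$elapsed)
  invisible(res)
}

#' Write pipeline outputs to a run directory
#'
#' Writes the cohort table, atlas, gradient values, centiles, hierarchy
#' scores, trajectory curves, age-bin and mediation tables as delimited
#' text, plus a JSON manifest carrying the configuration and its hash.
#'
#' @param res result list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(res$cohort, "cohort.csv")
  write_atlas(res$atlas, file.path(out_dir, "atlas.tsv"))
  w(data.frame(subject_id = res$cohort$subject_id, res$G1,
               check.names = FALSE), "gradient_g1.csv")
  w(data.frame(subject_id = res$cohort$subject_id, res$centiles,
               check.names = FALSE), "centiles.csv")
  w(res$scores, "hierarchy_scores.csv")
  w(res$age_tests, "age_effect_tests.csv")
  for (g in names(res$trajectories))
    w(res$trajectories[[g]]$curves, sprintf("trajectory_%s.csv", g))
  w(res$bin_table, "age_bin_networks.csv")
  if (!is.null(res$behavior)) w(res$behavior, "behavior_correlation.csv")
  w(data.frame(subject_id = res$cohort$subject_id, res$pc_table,
               check.names = FALSE), "pc_summaries.csv")
  w(data.frame(subject_id = res$cohort$subject_id, res$pc_ref,
               check.names = FALSE), "pc_centiles_reference.csv")
  w(res$pc_trend, "pc_age_trend.csv")
  w(res$mediation, "mediation.csv")
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(res$config, cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("gradnorm")),
    config_hash = unname(tools::md5sum(cfg_path)),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Generate the bundled synthetic fixtures
#'
#' `"tiny"` (P = 20, 10 + 10 subjects) exercises every stage in seconds;
#' `"demo"` (P = 200, 300 + 300) is the reference study-scale cohort.
#' Repeated calls with the same size write identical files.
#'
#' @param size `"tiny"` or `"demo"`.
#' @param dir output directory.
#' @return the run result list, invisibly.
#' @export
make_fixtures <- function(size = c("tiny", "demo"), dir = tempfile()) {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = pipeline_config(P = 20, n_td = 10, n_asd = 10, k = 3,
                           n_boot = 200, seed = 42L),
    demo = pipeline_config(seed = 42L))
  run_pipeline(cfg, out_dir = dir, verbose = FALSE)
}

# ---- small text I/O helpers ----

#' Read/write square matrices and atlases as plain text
#'
#' Matrices are whitespace-delimited text; atlases are two-column TSV
#' (parcel_id, network).
#'
#' @param m numeric matrix.
#' @param path file path.
#' @name text_io
#' @export
write_matrix <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
}

#' @rdname text_io
#' @export
read_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname text_io
#' @param atlas a `parcel_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @rdname text_io
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  network <- factor(df$network, levels = YEO7_NETWORKS)
  if (anyNA(network)) stop("unknown network labels in atlas file",
                           call. = FALSE)
  structure(list(parcel_id = df$parcel_id, network_of = network,
                 P = nrow(df)), class = "parcel_atlas")
}
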