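# Shared study configuration for the numbered analysis scripts.
# Connectivity matrices are regenerated deterministically from the seed,
# so scripts exchange only small tables under results/.

library(gradnorm)

STUDY <- pipeline_config(P = 200, n_td = 300, n_asd = 300, k = 5,
                         n_boot = 5000, seed = 42L)

results_path <- function(name) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", name)
}

need_result <- function(name) {
  p <- results_path(name)
  if (!file.exists(p))
    stop("missing ", p, " - run the earlier analysis scripts first",
         call. = FALSE)
  utils::read.csv(p, check.names = FALSE)
}

# rebuild the generator state (atlas, truth, cohort, matrices)
rebuild_simulation <- function(cfg = STUDY) {
  atlas <- make_atlas(cfg$P)
  truth <- do.call(sim_truth, c(list(atlas = atlas, seed = cfg$seed),
                                cfg$truth_args))
  cohort <- simulate_cohort(cfg$n_td, cfg$n_asd, truth)
  sim <- simulate_cohort_connectivity(cohort, truth, atlas)
  cohort <- simulate_symptoms(cohort, sim$truth_table$alignment,
                              cfg$rho_symptoms, seed = cfg$seed + 11L)
  list(atlas = atlas, truth = truth, cohort = cohort,
       matrices = sim$matrices, truth_table = sim$truth_table)
}
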