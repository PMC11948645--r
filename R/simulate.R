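# Synthetic cohort generator. Every downstream stage of the pipeline is
# validated against the ground truth planted here. Each subject's
# connectivity carries a rank-1 gradient term s^2 * u u' built from a
# unit direction u = sqrt(1 - beta^2) g0 + beta e (the template
# sensory-DMN axis plus axis noise beta) and an expression scale s that
# grows with age (gradient expansion). The ASD deviation has two arms
# sharing one inverted-U severity profile that vanishes at the catch-up
# (peak) age: (i) multiplicative attenuation of the expression scale —
# the suppressed-gradient phenotype, which contracts the embedded
# gradient and yields the childhood sensory/attention-up, DMN-down
# centile pattern; and (ii) a small axis-noise excess, which lowers the
# hierarchy score. Older ASD subjects additionally carry a weakened
# within-DMN block whose severity latent drives both DMN participation
# and extra axis noise — the planted mediated pathway.

# run expr under a temporary RNG state so generators are deterministic
# under their seed without clobbering the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Ground-truth parameters for the synthetic cohort generator
#'
#' Bundles every generator parameter: the template gradient built from the
#' atlas (sensory parcels at the negative pole, DMN at the positive pole),
#' the age-related expansion of gradient expression, the group alignment
#' trajectories, connectivity mixture weights and noise levels, and the
#' planted childhood centile pattern and late-adolescent DMN mediation
#' effect. Defaults are the package's reference study conditions; see the
#' methods vignette for the rationale behind each value.
#'
#' @param atlas a `parcel_atlas`.
#' @param age_range cohort age range in years.
#' @param expansion_rate per-year increase of the gradient expression
#'   scale `s(age) = 1 + expansion_rate * (age - age_min)`.
#' @param axis_noise_base,axis_noise_slope TD axis-noise magnitude
#'   `beta` at `age_min` and its per-year change (negative: the
#'   individual axis converges to the template with age; the cosine
#'   alignment is `sqrt(1 - beta^2)`).
#' @param axis_sd_td0,axis_sd_td_slope subject-level SD of TD axis noise
#'   at `age_min` and its per-year change (negative = narrowing with
#'   age, the TD-typical sigma trend).
#' @param axis_sd_asd subject-level SD of ASD axis noise (constant).
#' @param peak_age age at which the ASD deviation vanishes (catch-up).
#' @param dev_curv curvature of the ASD inverted-U deficit: ASD mean
#'   axis noise is `beta_td(age) + dev_curv * (age - peak_age)^2`,
#'   running parallel to the TD curve and touching it at `peak_age`.
#' @param med_start,med_ramp,med_base,med_load,med_beta parameters of
#'   the planted DMN mediation in ASD: from age `med_start` the effect
#'   ramps in linearly over `med_ramp` years. At full strength the whole
#'   within-DMN connectivity block is multiplied by
#'   `1 - med_base - med_load * u` for a standard-normal severity latent
#'   `u` (weakened within-DMN connectivity), with the DMN's
#'   between-network couplings boosted by `med_gain` times the removed
#'   fraction — segregation loss redistributes DMN edges outward rather
#'   than releasing them globally — and the same latent adds
#'   `med_beta * (u + 1)` to the subject's axis noise, the score-side
#'   arm of the mediated pathway.
#' @param med_gain between-coupling boost per unit of within-DMN
#'   weakening.
#' @param gradient_weight weight of the rank-1 gradient term; the term's
#'   entries are `gradient_weight * s(age)^2 * P * u u'` for the unit
#'   planted direction `u`, putting them on the Fisher-z scale of real
#'   connectivity.
#' @param module_strength within-network connectivity block weight
#'   (Fisher-z units).
#' @param between_strength base weight of the fixed between-network
#'   coupling blocks (axis-adjacent and canonically interacting network
#'   pairs); these give every parcel cross-module edges in the
#'   binarized graph, as in real connectomes.
#' @param module_h_sd SD of the fixed pair-level heterogeneity of the
#'   within-network blocks (drawn once per truth; shared by all
#'   subjects). Heterogeneous within-module strength lets only part of
#'   each module's pairs enter the thresholded graphs, as in real
#'   connectomes.
#' @param module_jitter_sd subject-by-network SD of the multiplicative
#'   jitter on the block weight.
#' @param noise_sd SD of the symmetric additive connectivity noise.
#' @param site_sd SD of additive per-site offsets on connectivity
#'   (0 disables site effects).
#' @param n_sites number of acquisition sites.
#' @param seed base seed; all per-subject draws derive from it.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(atlas,
                      age_range = c(5, 22),
                      expansion_rate = 0.025,
                      axis_noise_base = 0.25, axis_noise_slope = -0.006,
                      axis_sd_td0 = 0.04, axis_sd_td_slope = -0.0015,
                      axis_sd_asd = 0.04,
                      peak_age = 15, dev_curv = 0.0009,
                      atten_curv = 0.0035, atten_sd = 0.03,
                      med_start = 15, med_ramp = 4,
                      med_base = 0.18, med_load = 0.12,
                      med_beta = 0.05, med_gain = 0,
                      gradient_weight = 0.25, module_strength = 0.20,
                      between_strength = 0.12,
                      module_h_sd = 0.5, module_jitter_sd = 0.15,
                      noise_sd = 0.08,
                      site_sd = 0, n_sites = 1,
                      seed = 1L) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (diff(age_range) <= 0) stop("degenerate age range", call. = FALSE)
  # template axis: network-level anchors from sensory (negative) to DMN
  # (positive) with a small deterministic within-network spread
  anchors <- c(Visual = -1.0, Somatomotor = -0.8, DorsalAttention = -0.6,
               VentralAttention = -0.45, Limbic = 0.15, Control = 0.55,
               DMN = 1.0)
  g0 <- anchors[as.character(atlas$network_of)]
  for (nw in levels(atlas$network_of)) {
    idx <- which(atlas$network_of == nw)
    if (length(idx) > 1)
      g0[idx] <- g0[idx] + seq(-0.15, 0.15, length.out = length(idx))
  }
  g0 <- as.numeric(g0 - mean(g0))

  # fixed pair-level heterogeneity of the within-network blocks
  module_h <- .with_seed(seed + 333L, {
    lapply(stats::setNames(nm = levels(atlas$network_of)), function(nw) {
      k <- sum(atlas$network_of == nw)
      H <- matrix(abs(stats::rnorm(k * k, 1, module_h_sd)), k, k)
      (H + t(H)) / 2
    })
  })
  # canonical between-network couplings (axis neighbors and known
  # interacting systems), with fixed parcel-pair heterogeneity
  nets <- levels(atlas$network_of)
  bw <- matrix(0, 7, 7, dimnames = list(nets, nets))
  couple <- function(a, b, w) {
    bw[a, b] <<- w; bw[b, a] <<- w
  }
  couple("Visual", "Somatomotor", 1.0)
  couple("Somatomotor", "DorsalAttention", 1.0)
  couple("DorsalAttention", "VentralAttention", 1.0)
  couple("VentralAttention", "Control", 0.8)
  couple("Control", "DMN", 1.0)
  couple("Limbic", "DMN", 0.6)
  couple("Limbic", "Control", 0.5)
  couple("VentralAttention", "DMN", 0.4)
  couple("Visual", "DorsalAttention", 0.5)
  between_h <- .with_seed(seed + 444L, {
    out <- list()
    for (i in 1:6) for (j in (i + 1):7) {
      if (bw[i, j] > 0) {
        ki <- sum(atlas$network_of == nets[i])
        kj <- sum(atlas$network_of == nets[j])
        out[[paste(nets[i], nets[j], sep = ".")]] <-
          matrix(abs(stats::rnorm(ki * kj, 1, module_h_sd)), ki, kj)
      }
    }
    out
  })

  beta_td <- function(age)
    pmax(axis_noise_base + axis_noise_slope * (age - age_range[1]), 0)
  beta_asd <- function(age)
    beta_td(age) + dev_curv * (age - peak_age)^2
  align_of <- function(beta) sqrt(pmax(1 - beta^2, 0))

  structure(list(
    template_gradient = g0,
    P = atlas$P,
    age_range = age_range,
    expansion_fn = function(age)
      1 + expansion_rate * (age - age_range[1]),
    beta_td = beta_td,
    beta_asd = beta_asd,
    align_td = function(age) align_of(beta_td(age)),
    align_asd = function(age) align_of(beta_asd(age)),
    deviation_fn = function(age) align_of(beta_asd(age)) /
      align_of(beta_td(age)),
    axis_sd_td = function(age)
      pmax(axis_sd_td0 + axis_sd_td_slope * (age - age_range[1]), 0),
    axis_sd_asd = axis_sd_asd,
    peak_age = peak_age, dev_curv = dev_curv,
    atten_curv = atten_curv, atten_sd = atten_sd,
    atten_fn = function(age)
      pmax(1 - atten_curv * pmax(peak_age - age, 0)^2, 0.2),
    med_start = med_start, med_ramp = med_ramp,
    med_base = med_base, med_load = med_load,
    med_beta = med_beta, med_gain = med_gain,
    gradient_weight = gradient_weight,
    module_strength = module_strength, module_h = module_h,
    between_strength = between_strength, between_w = bw,
    between_h = between_h,
    module_jitter_sd = module_jitter_sd,
    noise_sd = noise_sd,
    site_sd = site_sd, n_sites = n_sites,
    seed = as.integer(seed)
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: P = %d, ages %.0f-%.0f, ASD peak age %.1f, noise_sd %.3f\n",
    x$P, x$age_range[1], x$age_range[2], x$peak_age, x$noise_sd))
  invisible(x)
}

#' Simulate a cohort phenotype table
#'
#' Draws ages (uniform by default; `"skewed"` mimics the sparse sampling
#' of older participants typical of developmental cohorts), balanced sexes
#' in expectation, group labels and site assignments.
#'
#' @param n_td,n_asd group sizes.
#' @param truth a `sim_truth`.
#' @param age_dist `"uniform"` or `"skewed"` (Beta(1.2, 2.2)-shaped, denser
#'   at young ages).
#' @param seed overrides `truth$seed`.
#' @return data.frame with columns subject_id, age, sex, group, site.
#' @export
simulate_cohort <- function(n_td, n_asd, truth,
                            age_dist = c("uniform", "skewed"),
                            seed = NULL) {
  age_dist <- match.arg(age_dist)
  if (n_td < 0 || n_asd < 0) stop("negative group size", call. = FALSE)
  n <- n_td + n_asd
  seed <- seed %||% truth$seed
  lo <- truth$age_range[1]; hi <- truth$age_range[2]
  .with_seed(seed, {
    age <- if (age_dist == "uniform") stats::runif(n, lo, hi)
           else lo + (hi - lo) * stats::rbeta(n, 1.2, 2.2)
    sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
    site <- sprintf("site_%02d", sample.int(truth$n_sites, n, replace = TRUE))
  })
  out <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = age,
    sex = sex,
    group = factor(rep(c("TD", "ASD"), c(n_td, n_asd)),
                   levels = c("TD", "ASD")),
    site = site,
    stringsAsFactors = FALSE
  )
  if (n == 0) out <- out[0, ]
  out
}

# latent per-subject gradient truth: axis-noise magnitude, direction,
# module multipliers and the mediation severity latent
.subject_latents <- function(subject, truth, atlas, seed) {
  P <- truth$P
  g0 <- truth$template_gradient
  g0u <- g0 / sqrt(sum(g0^2))
  is_asd <- as.character(subject$group) == "ASD"
  age <- subject$age
  .with_seed(seed, {
    u_med <- stats::rnorm(1)
    ramp <- if (is_asd && truth$med_ramp > 0)
      min(max((age - truth$med_start) / truth$med_ramp, 0), 1)
      else as.numeric(is_asd && age >= truth$med_start)
    mediated <- ramp > 0 && (truth$med_base > 0 || truth$med_beta > 0)
    bbar <- if (is_asd) truth$beta_asd(age) else truth$beta_td(age)
    bsd <- if (is_asd) truth$axis_sd_asd else truth$axis_sd_td(age)
    beta <- bbar + bsd * stats::rnorm(1)
    if (mediated) beta <- beta + ramp * truth$med_beta * (u_med + 1)
    beta <- min(max(beta, 0), 0.95)
    e <- stats::rnorm(P)
    e <- e - sum(e * g0u) * g0u
    e <- e / sqrt(sum(e^2))
    u_vec <- sqrt(1 - beta^2) * g0u + beta * e
    # attenuation arm: suppressed gradient expression in ASD
    atten <- 1
    if (is_asd && truth$atten_curv > 0) {
      atten <- truth$atten_fn(age) + truth$atten_sd * stats::rnorm(1)
      atten <- min(max(atten, 0.2), 1.2)
    }
    # per-network multiplicative jitter on the within-module block
    mods <- 1 + truth$module_jitter_sd * stats::rnorm(nlevels(atlas$network_of))
    names(mods) <- levels(atlas$network_of)
    pair_jit <- 1 + truth$module_jitter_sd *
      stats::rnorm(length(truth$between_h))
    names(pair_jit) <- names(truth$between_h)
    list(beta = beta,
         alignment = sum(u_vec * g0u),
         direction = u_vec,
         scale = truth$expansion_fn(age) * atten,
         atten = atten,
         modules = mods,
         pair_jitter = pair_jit,
         dmn_mult = if (mediated && truth$med_base > 0)
           max(1 - ramp * (truth$med_base + truth$med_load * u_med), 0.1)
           else 1,
         u_med = if (mediated) u_med else NA_real_)
  })
}

#' Simulate one subject's connectivity matrix
#'
#' Builds a symmetric Fisher-z connectivity matrix as a weighted sum of a
#' rank-1 gradient term (outer product of the subject's scaled planted
#' gradient), a within-network block term, and symmetric Gaussian noise.
#' The planted gradient is `s(age)` times a unit direction whose cosine
#' with the template axis equals the subject's planted alignment, so the
#' embedding stage has an exactly known target.
#'
#' @param subject one row of a cohort table (needs age, sex, group, and
#'   optionally site).
#' @param truth a `sim_truth`.
#' @param atlas the `parcel_atlas` the truth was built from.
#' @param seed per-subject seed.
#' @return P-by-P matrix with attributes `alignment` (planted cosine with
#'   the template axis), `scale`, `modules` and `u_med`.
#' @export
simulate_connectivity <- function(subject, truth, atlas, seed) {
  stopifnot(inherits(truth, "sim_truth"), inherits(atlas, "parcel_atlas"))
  if (is.null(subject$age) || is.null(subject$group))
    stop("subject row must carry age and group", call. = FALSE)
  P <- truth$P
  lat <- .subject_latents(subject, truth, atlas, seed)
  W <- truth$gradient_weight * lat$scale^2 * P *
    outer(lat$direction, lat$direction)
  for (nw in levels(atlas$network_of)) {
    idx <- which(atlas$network_of == nw)
    W[idx, idx] <- W[idx, idx] +
      truth$module_strength * lat$modules[nw] * truth$module_h[[nw]]
  }
  dmn_gain <- 1 + truth$med_gain * (1 - lat$dmn_mult)
  for (pr in names(truth$between_h)) {
    ab <- strsplit(pr, ".", fixed = TRUE)[[1]]
    ia <- which(atlas$network_of == ab[1])
    ib <- which(atlas$network_of == ab[2])
    blk <- truth$between_strength * truth$between_w[ab[1], ab[2]] *
      lat$pair_jitter[pr] * truth$between_h[[pr]]
    if ("DMN" %in% ab) blk <- blk * dmn_gain
    W[ia, ib] <- W[ia, ib] + blk
    W[ib, ia] <- W[ib, ia] + t(blk)
  }
  # planted mediation: weakened within-DMN connectivity (gradient and
  # module contributions alike), i.e. reduced DMN segregation
  if (lat$dmn_mult != 1) {
    dmn <- which(atlas$network_of == "DMN")
    W[dmn, dmn] <- W[dmn, dmn] * lat$dmn_mult
  }
  if (truth$noise_sd > 0) {
    E <- .with_seed(seed + 500003L,
                    matrix(stats::rnorm(P * P), P, P))
    W <- W + truth$noise_sd * (E + t(E)) / sqrt(2)
  }
  if (truth$site_sd > 0 && !is.null(subject$site)) {
    site_num <- as.integer(factor(subject$site,
                                  sprintf("site_%02d", 1:truth$n_sites)))
    off <- .with_seed(truth$seed + 900007L,
                      stats::rnorm(truth$n_sites, 0, truth$site_sd))
    W <- W + off[site_num]
  }
  diag(W) <- 0
  dimnames(W) <- list(atlas$parcel_id, atlas$parcel_id)
  attr(W, "alignment") <- lat$alignment
  attr(W, "beta") <- lat$beta
  attr(W, "scale") <- lat$scale
  attr(W, "modules") <- lat$modules
  attr(W, "dmn_mult") <- lat$dmn_mult
  attr(W, "u_med") <- lat$u_med
  W
}

#' Simulate connectivity for a whole cohort
#'
#' @param cohort a cohort table from [simulate_cohort()].
#' @param truth,atlas generator truth and atlas.
#' @return list with `matrices` (list of P-by-P matrices, one per subject)
#'   and `truth_table` (data.frame of planted per-subject alignment,
#'   expression scale and mediation latent).
#' @export
simulate_cohort_connectivity <- function(cohort, truth, atlas) {
  mats <- vector("list", nrow(cohort))
  tt <- data.frame(subject_id = cohort$subject_id,
                   alignment = NA_real_, beta = NA_real_,
                   scale = NA_real_, u_med = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cohort))) {
    W <- simulate_connectivity(cohort[i, ], truth, atlas,
                               seed = truth$seed + 1000L + i)
    tt$alignment[i] <- attr(W, "alignment")
    tt$beta[i] <- attr(W, "beta")
    tt$scale[i] <- attr(W, "scale")
    tt$u_med[i] <- attr(W, "u_med")
    mats[[i]] <- W
  }
  names(mats) <- cohort$subject_id
  list(matrices = mats, truth_table = tt)
}

#' Simulate a BOLD-like time series realizing a connectivity target
#'
#' Inverts the Fisher-z target to correlation space, shrinks it toward the
#' identity just enough to be positive definite (convex shrinkage with the
#' smallest sufficient weight, recorded as an attribute), and draws `T`
#' rows from the corresponding zero-mean multivariate normal. The sample
#' correlation converges to the (shrunken) target as `T` grows.
#'
#' @param connectivity P-by-P Fisher-z matrix (zero diagonal).
#' @param T number of timepoints (at least 2).
#' @param seed RNG seed.
#' @param min_eig smallest admissible eigenvalue of the target correlation.
#' @return T-by-P matrix with attribute `shrinkage`.
#' @export
simulate_timeseries <- function(connectivity, T, seed = 1L,
                                min_eig = 1e-6) {
  if (!is.numeric(T) || length(T) != 1 || T < 2)
    stop("'T' must be an integer >= 2", call. = FALSE)
  R <- tanh(as.matrix(connectivity))
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  w <- 0
  if (lam_min < min_eig) {
    w <- (min_eig - lam_min) / (1 - lam_min)
    R <- (1 - w) * R + w * diag(nrow(R))
  }
  U <- chol(R)
  X <- .with_seed(seed,
                  matrix(stats::rnorm(T * nrow(R)), T, nrow(R))) %*% U
  attr(X, "shrinkage") <- w
  X
}

#' Attach symptom scores correlated with the planted hierarchy alignment
#'
#' Generates a total symptom score with target correlation `rho` against
#' the planted per-subject hierarchy alignment, plus five subscores that
#' are noisy copies of the total, all on a T-score-like scale
#' (mean 60, SD 10).
#'
#' @param cohort cohort table.
#' @param hierarchy_truth numeric vector of planted alignments (e.g. the
#'   `alignment` column of [simulate_cohort_connectivity()]'s truth table).
#' @param rho target correlation in \[-1, 1\] (negative for the
#'   severity-vs-hierarchy relation).
#' @param seed RNG seed.
#' @param subscore_noise_sd SD of the subscore perturbation on the z scale
#'   (0 makes subscores identical to the total).
#' @return the cohort with columns `srs_total` and `srs_1` .. `srs_5`.
#' @export
simulate_symptoms <- function(cohort, hierarchy_truth, rho, seed = 1L,
                              subscore_noise_sd = 0.3) {
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]", call. = FALSE)
  n <- nrow(cohort)
  stopifnot(length(hierarchy_truth) == n)
  z <- as.numeric(scale(hierarchy_truth))
  .with_seed(seed, {
    base <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    cohort$srs_total <- 60 + 10 * base
    for (j in 1:5)
      cohort[[paste0("srs_", j)]] <-
        60 + 10 * (base + subscore_noise_sd * stats::rnorm(n))
  })
  cohort
}
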