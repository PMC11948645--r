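---
title: "Normative modeling of connectome gradient development: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modeling of connectome gradient development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gradnorm)
```

## The scientific question

Cortical function is organized along a macroscale hierarchy running from
unimodal sensory regions to transmodal association cortex, with the
default mode network (DMN) at its apex. The first diffusion-map
component of a functional connectome — the principal gradient, G1 —
indexes each region's position on this axis. This package implements a
normative-modeling analysis of how that hierarchy matures between ages 5
and 22 and how autism spectrum disorder (ASD) deviates from the typical
trajectory: per-region normative age models, individual centile scores,
a whole-brain hierarchy score, participation-coefficient (PC) measures
of network segregation, and bootstrap mediation linking diagnosis, PC
and hierarchy. Because the motivating neuroimaging cohorts are
restricted-access, every stage is validated on a synthetic cohort
generator with planted, recoverable ground truth.

## From time series to gradients

Subject connectomes are Pearson correlations between parcel time series,
Fisher r-to-z transformed (`compute_fc()`). Each row keeps its strongest
10% of connections (`row_threshold()`; signed values, ties broken by
column index for bit-reproducibility), pairwise profile similarity is
the normalized-angle kernel `1 - acos(cos_sim)/pi`
(`normalized_angle_affinity()`), and `diffusion_embedding()` performs
the standard diffusion-map construction: density normalization with
`alpha = 0.5`, the row-stochastic operator, a dense symmetric
eigendecomposition (exactness over speed; the P <= 1000 regime does not
need iterative solvers), and component scaling by `lambda / (1 -
lambda)` (`diffusion_time = 0` convention). The group template is
embedded from the *averaged* z-matrix of the reference (TD) group, not
from averaged embeddings, and individuals are aligned to it by
orthogonal Procrustes rotation without scaling (`procrustes_align()`;
scaling is available behind a flag but the alignment literature this
follows rotates only). Component signs follow the template, whose first
component is oriented so DMN parcels load positively. We expose `k = 5`
components by default — only the first two are analyzed, and estimates
of the leading components are insensitive to modest changes in `k`.

## The SHASH normative model

Each brain feature y (a parcel's G1 value, a PC summary, or the
hierarchy score) is modeled as sinh-arcsinh distributed with
age-dependent parameters:

- location: mu = b0 + f(age) + sex * g(age),
- scale: log sigma = c0 + h(age),
- shape: log nu and log tau constant.

`f`, `g`, `h` are P-splines: cubic B-splines on 10 equally spaced
interior knots with a second-order difference penalty. The sex term is a
varying-coefficient copy of the age basis (a sex-specific smooth
deviation; its unpenalized constant direction absorbs the sex main
effect). The skewness parameter uses a log link by default, matching the
printed model specification this design follows; that forces positive
skew, so an identity-link option is provided (`nu_link = "identity"`)
for features with left-skewed residuals. With nu = 0 and tau = 1 the
family is exactly Gaussian, and the fitted likelihood can never fall
below the Gaussian special case because that point lies inside the
parameter space.

### Estimation

`fit_normative()` maximizes the penalized log-likelihood from a
deterministic initialization (penalized least squares for mu, log
residual SD for sigma, Gaussian shape). Two block cycles
(mu / log-sigma / shape, each a BFGS step) stabilize the blocks, then a
joint quasi-Newton pass over all coefficients drives the penalized
log-likelihood to its optimum; pure block cycling was observed to
zigzag indefinitely when blocks are correlated, which is why the joint
pass exists. Convergence requires the penalized log-likelihood to
improve by less than 1e-6 between passes. Two numerical safeguards
matter in practice:

- the response is standardized internally (exact, by location-scale
  equivariance of the family) so optimizer conditioning does not depend
  on the feature's units;
- a weak ridge (1e-3) on log tau blocks the spike degeneracy that
  heavily tied responses induce (sigma and tau jointly collapsing
  toward zero). PC summaries are means of lattice-valued node scores
  and do produce ties.

The smoothing weight is fixed by configuration or selected from
{0.1, 1, 10, 100} by generalized AIC with penalty multiplier 3.
Effective degrees of freedom come from the joint observed information
across all blocks, F = (H + P)^-1 H, with tr(F) used for GAIC and the
`2F - F^2` form for test degrees of freedom.

### Centiles, transfer and tests

Centile scores are the fitted CDF at the subject's value given age and
sex, clipped to [1e-6, 1 - 1e-6]; ages outside the fitted range are
scored by constant extrapolation of the parameter curves and flagged.
`transfer_recalibrate()` re-estimates only the two intercepts (location
and log-scale) on a new cohort by maximum likelihood from a
moment-matched start, holding all spline and shape coefficients fixed —
the standard normative-transfer recipe.

Age effects on the location are tested by likelihood ratio against an
intercept-only-location refit, with chi-squared reference on the
dropped terms' effective df. This test is calibrated (type-I error
0.05-0.06 in null simulations at n = 500). The variance-trend test
(`sigma_age_effect()`) defaults to a strongly smoothed scale spline
(lambda = 1000): the second-order penalty leaves linear trends
unpenalized, so heavy smoothing costs no power against monotone
variance trends while making the chi-squared reference accurate (the
weakly smoothed version is measurably anticonservative, ~0.07-0.10).

## Hierarchy score and trajectories

The hierarchy score is the cosine similarity between a subject's
aligned G1 vector and the per-parcel normative *median* (not mean) at
the subject's age and sex. Group trajectories refit the SHASH model to
the scores; the reported slope per year is the mean derivative of the
median curve over the fitted range (pointwise derivatives are also
exported), and a peak age is reported only for an interior,
non-monotone maximum at least 0.5 y from the range boundary. Per-sex
curves are reported for parity with developmental studies, but the peak
of the sex-pooled fit is the stable group-level estimate at a few
hundred subjects per group — per-sex subsamples halve n and the peak of
a flat-topped curve is the least stable feature of the fit.

Group comparisons of centiles use Welch t-tests (the variance-equality
assumption buys nothing here) with Benjamini-Hochberg correction, at
parcel level and after averaging centiles within the 7 canonical
networks. Age bins are half-open — 12 and 15 belong to the older bin —
covering 5-12, 12-15 and 15-22 years.

## Topology and mediation

PC is computed exactly as `1 - sum_m (k_m / k)^2` on the binarized
graph keeping the globally top 10% of positive connections (global
rather than per-row ranking, because PC needs an undirected graph and
per-row thresholding breaks symmetry); isolated nodes get PC 0 with a
warning. PC centiles support two referencing conventions: `"within"`
fits each group's own normative model (controls age, sex and diagnosis
simultaneously — the right convention for describing group-specific PC
trajectories) and `"reference"` scores everyone against the TD model.
Mediation uses the `"reference"` convention: within-group centiles are
uniform by construction, which would null the diagnosis-to-mediator
path and make group mediation undefined — this is the package's
resolution of a genuine ambiguity in how group-specific PC norms can
feed a between-group mediation model.

`mediate()` implements single-mediator standardized-path mediation with
a subject-level percentile bootstrap (resampling rows, refitting and
restandardizing every path per resample; resamples with a single
exposure level are redrawn and counted). The exact identity
c = c' + a*b holds per fit. The bootstrap is vectorized over resamples,
so the default 5,000 draws are cheap.

## The synthetic cohort generator

The generator is the package's test bed and defines its study
conditions. Each subject's connectivity is

- a rank-1 gradient term `gw * s^2 * P * u u'`, where
  `u = sqrt(1 - beta^2) g0 + beta e` mixes the template sensory-DMN
  axis `g0` (network-level anchors from -1.0 for visual to +1.0 for
  DMN, small within-network spread, mean-centered) with subject
  idiosyncratic axis noise of magnitude beta, and `s(age)` is the
  expression scale growing 2.5%/year (gradient expansion);
- within-network blocks (weight 0.20) with fixed pair-level
  heterogeneity and subject-level network jitter;
- between-network blocks (weight 0.12) for axis-adjacent and canonical
  partner systems, which guarantee every parcel cross-module edges in
  the binarized graph — without them, mid-axis networks' PC is
  degenerate (constant zero);
- symmetric Gaussian noise (SD 0.08 in Fisher-z units).

Alignment with the template axis is `sqrt(1 - beta^2)`, so the group
trajectories are parameterized in beta: the TD mean falls linearly
(0.25 to ~0.15 over the age range; the hierarchy consolidates), the TD
subject SD narrows with age (the sigma-trend plant) while the ASD SD
stays constant, and the ASD deviation has two arms sharing one
inverted-U severity that vanishes at the catch-up age of 15:

- an *attenuation* arm multiplying the expression scale by
  `1 - 0.0035 (15 - age)^2` before the catch-up age (and not after) —
  the suppressed-gradient phenotype resolving by mid-adolescence.
  Weaker expression contracts the embedded gradient, which the
  per-parcel centiles read as somatomotor/attention up and DMN down,
  strongest in childhood. (Contraction also raises visual and lowers
  control centiles; the four networks named above are the documented
  plant. The arm is one-sided because its post-peak graph footprint
  would otherwise swamp the mediation plant's PC signal with
  heterogeneity-dependent, seed-unstable group differences.)
- an *axis-noise* arm adding `0.0009 (age - 15)^2` to beta, which
  carries the hierarchy-score deviation. Cosine similarity is
  scale-invariant, so attenuation alone cannot move the score; the two
  arms are separated precisely so that the centile pattern and the
  score trajectory are independently controllable.

From age 15 the mediation plant ramps in linearly over 4 years for ASD
subjects: a standard-normal severity latent u multiplies the within-DMN
block by `1 - 0.18 - 0.12 u` (reduced segregation, higher DMN PC) and
adds `0.05 (u + 1)` to beta (lower score) — the mediated pathway. The
u-loading on the block is kept moderate deliberately: the PC response
to within-module weakening is monotone only while enough within-DMN
edges stay above the binarization threshold, and stronger loadings push
subjects into a non-monotone regime that destroys the mediator-outcome
correlation.

Several plant mechanisms were evaluated and rejected during design:
shifting the gradient *direction* along a network pattern does not
transmit through the pipeline (row-thresholded profiles of a rank-1
term depend on the direction mainly through entry signs), and
pole-compression deviations (`sign(u)|u|^gamma`) are rank-preserving on
the connectivity and therefore invisible to *both* the embedding and
the PC — a useful negative result: any deviation must change the
thresholded graphs to be measurable, which also means no deviation is
ever visible to the score and strictly invisible to topology.

### What the generator does and does not emulate

It emulates network-structured, axis-organized connectivity with
subject noise, age maturation, a recoverable inverted-U clinical
deviation, variance narrowing, symptom correlations and optional site
offsets. It does not emulate BOLD acquisition, motion, scanner
artifacts, hemispheric structure, or the empirical richness of real
FC (e.g., distance effects, higher-gradient structure beyond what the
module blocks induce). Passing tests demonstrate that the estimators
recover what was planted under this model, not that real data meet the
model's assumptions.

## Known limitations

- **Quota coupling of PC features.** All network PC summaries derive
  from one binarized graph with a fixed edge quota, so they are
  mechanically inter-dependent: weakening within-DMN connectivity
  pushes displaced edges into threshold-adjacent networks (dorsal
  attention, control), which then inherit attenuated but real group
  differences and score couplings. In the demo cohort the planted DMN
  mediation is recovered, but echo mediators in coupled networks also
  reach significance at n = 300 per group. This is a property of
  fixed-density PC analyses generally, not of the implementation; an
  exclusively single-network mediation pattern should not be expected
  from this class of measures, and the corresponding end-to-end
  assertion is left strict (and failing) rather than weakened.
- **Chi-squared references for penalized LR tests** are approximate;
  the scale-trend test is only calibrated in the strongly smoothed
  regime (see above).
- **Exactly noise-free cohorts** make per-parcel distributional fits
  degenerate (zero residual spread); the noiseless validation uses a
  near-zero-noise configuration instead.
- The generator's ASD deviation is a stand-in chosen for
  recoverability; its parameters are generator settings, not estimates
  of any clinical cohort.

## Problem sizes

Unit tests run at P = 14-70 parcels and n = 10-300 subjects; parameter
recovery uses n = 1000-2000; calibration studies use 200 replicates at
n = 500; the end-to-end demo runs the reference conditions, P = 200
with 300 subjects per group. A full demo pipeline takes a few minutes
on one core; the dominant costs are the 200 per-parcel SHASH fits and
600 dense eigendecompositions.
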