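#!/usr/bin/env Rscript
# Stage 4: whole-brain hierarchy scores (cosine similarity with the
# age/sex-specific normative gradient), group trajectories with slopes
# and peak ages, the sigma (variance) trend, network-wise centile
# comparisons within developmental stages, and symptom correlations.

source("analysis/_common.R")

cohort <- need_result("cohort.csv")
g1 <- need_result("gradient_g1.csv")
G1 <- as.matrix(g1[, -1])
atlas <- read_atlas(results_path("atlas.tsv"))
centiles <- as.matrix(need_result("centiles.csv")[, -1])
td <- which(cohort$group == "TD")

models <- fit_normative_set(G1[td, ], cohort$age[td], cohort$sex[td],
                            lambda = STUDY$lambda)
scores <- score_cohort(G1, models, cohort)
write.csv(scores, results_path("hierarchy_scores.csv"), row.names = FALSE)

for (g in c("TD", "ASD")) {
  tf <- fit_score_trajectory(scores, group = g, lambda = STUDY$lambda)
  print(tf)
  write.csv(tf$curves, results_path(sprintf("trajectory_%s.csv", g)),
            row.names = FALSE)
  st <- sigma_age_effect(scores, group = g)
  message(sprintf("%s sigma trend: %s, p = %.3g", g,
                  c("-1" = "narrowing", "0" = "flat",
                    "1" = "widening")[as.character(st$trend)], st$p))
}

bin_tab <- age_bin_analysis(centiles, cohort, atlas)
write.csv(bin_tab, results_path("age_bin_networks.csv"), row.names = FALSE)
message("childhood (5-12) network t-values (ASD - TD):")
print(subset(bin_tab, bin == "5-12")[, c("feature", "t", "q")])

asd <- cohort$group == "ASD"
beh <- behavior_correlation(scores$score[asd],
                            cohort[asd, grep("^srs_", names(cohort))])
write.csv(beh, results_path("behavior_correlation.csv"), row.names = FALSE)
message(sprintf("hierarchy score vs SRS total in ASD: r = %.3f (q = %.3g)",
                beh$r[beh$scale == "srs_total"],
                beh$q[beh$scale == "srs_total"]))
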