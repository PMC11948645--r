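#!/usr/bin/env Rscript
# Stage 3: per-parcel SHASH normative models of age (and age-by-sex) fit
# on the TD group; everyone is scored as centiles of the TD normative
# distribution; regional age effects are tested by likelihood ratio with
# FDR correction.

source("analysis/_common.R")

cohort <- need_result("cohort.csv")
g1 <- need_result("gradient_g1.csv")
G1 <- as.matrix(g1[, -1])
td <- which(cohort$group == "TD")

models <- fit_normative_set(G1[td, ], cohort$age[td], cohort$sex[td],
                            lambda = STUDY$lambda)
centiles <- centile_scores(models, G1, cohort$age, cohort$sex)
write.csv(data.frame(subject_id = cohort$subject_id, centiles,
                     check.names = FALSE),
          results_path("centiles.csv"), row.names = FALSE)

age_tests <- do.call(rbind, lapply(seq_along(models), function(j) {
  tst <- age_effect_test(models[[j]], G1[td, j], cohort$age[td],
                         cohort$sex[td])
  data.frame(parcel = colnames(G1)[j], statistic = tst$statistic,
             df = tst$df, p = tst$p)
}))
age_tests$q <- p.adjust(age_tests$p, "BH")
write.csv(age_tests, results_path("age_effect_tests.csv"),
          row.names = FALSE)
message(sprintf("%d / %d parcels show a significant age effect (FDR < 0.05)",
                sum(age_tests$q < 0.05), nrow(age_tests)))
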