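#!/usr/bin/env Rscript

# Stage 5: prognostic value of the imaging subtypes.
#
# Kaplan-Meier curves and a log-rank test across subtypes, then a
# multivariable Cox model adjusting for stage, grade and sex (baselines:
# subtype 1, pT1, G1, female). Also tests the single spatial-relation
# feature (mean lymphocytes per tumor cell, core, r = 50) as a
# dichotomized stratifier. Writes results/km_curves.csv and
# results/cox.csv.

library(hespat)

clin <- read_clinical("results/cohort/clinical.csv")
sub <- read.csv("results/subtypes.csv")
clin$subtype <- as.character(sub$subtype[match(clin$specimen_id,
                                               sub$specimen_id)])

km <- km_logrank(clin, clin$subtype)
message(sprintf("log-rank across subtypes: chi2 = %.2f (df %d), p = %.4f",
                km$statistic, km$df, km$p))
write.csv(km$km, "results/km_curves.csv", row.names = FALSE)

cox <- cox_ph(clin, c("subtype", "stage", "grade", "sex"),
              baselines = list(subtype = "1", stage = "pT1", grade = "G1",
                               sex = "female"))
write.csv(cox, "results/cox.csv", row.names = FALSE)
message("multivariable Cox (Breslow ties):")
print(cox[, c("term", "HR", "lo95", "hi95", "p")], row.names = FALSE)

# a single tumor-lymphocyte relation feature as a stratifier
feats <- read.csv("results/features.csv", check.names = FALSE)
rel <- feats$tumor_lymph_relation_mean_CT[match(clin$specimen_id,
                                                feats$specimen_id)]
clin$til_high <- factor(ifelse(rel > median(rel), "high", "low"),
                        levels = c("low", "high"))
fit <- cox_ph(clin, "til_high")
message(sprintf(
  "high vs low lymphocytes-per-tumor-cell: HR = %.2f [%.2f-%.2f], p = %.4f",
  fit$HR, fit$lo95, fit$hi95, fit$p))
message("done.")
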