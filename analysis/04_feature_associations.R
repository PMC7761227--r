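#!/usr/bin/env Rscript

# Stage 4: which image features distinguish the subtypes?
#
# One-way ANOVA and Kruskal-Wallis per feature with Benjamini-Hochberg
# correction across all 246 features; chi-squared association of the
# subtypes with categorical clinical labels; correlation between tumor
# density and the tumor-lymphocyte relation. Writes
# results/associations.csv.

library(hespat)

feats <- read.csv("results/features.csv", check.names = FALSE)
X <- as.matrix(feats[, -1])
rownames(X) <- feats$specimen_id
sub <- read.csv("results/subtypes.csv")
labels <- sub$subtype[match(rownames(X), sub$specimen_id)]

res <- feature_subtype_tests(X, labels)
res <- res[order(res$anova_q), ]
write.csv(res, "results/associations.csv", row.names = FALSE)
message(sum(res$anova_q < 0.05, na.rm = TRUE),
        " of 246 features associated with the subtypes at FDR < 0.05")
message("headline features:")
print(res[res$feature %in%
            c("tumor_density_CT", "tumor_equivalent_diameter_mean",
              "tumor_quadrat_sd_CT", "lymph_quadrat_mean_CT",
              "lymph_quadrat_sd_CT", "tumor_lymph_relation_mean_CT"),
          c("feature", "anova_F", "anova_q", "kw_q")], row.names = FALSE)

# tumor density and peritumoral lymphocyte density measure different axes
corr <- pearson_corr(X[, "tumor_density_CT"],
                     X[, "tumor_lymph_relation_mean_CT"])
message(sprintf("tumor density vs lymphocytes-per-tumor-cell: r = %.2f (p = %.3g)",
                corr$r, corr$p))

clin <- read_clinical("results/cohort/clinical.csv")
clin <- clin[match(rownames(X), clin$specimen_id), ]
ct <- chisq_association(crosstab(labels, clin$stage))
message(sprintf("subtype x stage: chi2 = %.2f, df = %d, p = %.3f (expected null)",
                ct$statistic, ct$df, ct$p))
message("done; next: analysis/05_survival.R")
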