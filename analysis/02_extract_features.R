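#!/usr/bin/env Rscript

# Stage 2: extract the 246-feature spatial phenotype of every specimen.
#
# 150 nuclear features (morphometry, histogram, GLCM texture, color; mean
# and sd over tumor nuclei in the whole-tumor region), 28 density /
# homogeneity features, 64 tumor-lymphocyte interaction features (radii
# 50 and 100 px in core and periphery) and 4 composite counts. Writes
# results/features.csv and the machine-readable feature registry.

library(hespat)

cohort <- read_cohort("results/cohort")
message("extracting features for ", length(cohort$maps), " specimens ...")
t0 <- Sys.time()
X <- extract_cohort(cohort$maps, cohort$image_of)
message(sprintf("extracted %d x %d in %.1f s", nrow(X), ncol(X),
                as.numeric(Sys.time() - t0, units = "secs")))

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(specimen_id = rownames(X), X, check.names = FALSE),
          "results/features.csv", row.names = FALSE)
write_feature_registry("results/feature_registry.tsv")

message("headline features (cohort means):")
for (f in c("tumor_density_CT", "tumor_equivalent_diameter_mean",
            "lymph_density_CT", "tumor_lymph_relation_mean_CT"))
  message(sprintf("  %-34s %.3f", f, mean(X[, f])))
message("done; next: analysis/03_discover_subtypes.R")
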