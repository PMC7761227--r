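# The feature registry: stable names, categories and regions for the full
# 246-feature spatial phenotype.
#
# Patient-level counts by category: morphology 20, histogram 14, texture 62,
# color 54 (75 per-nucleus base descriptors x {mean, sd} over tumor nuclei
# in the whole-tumor region), density/homogeneity 28 (7 statistics x 2 cell
# classes x {core, periphery}), interaction 64 (8 statistics x 2 neighbor
# classes x 2 radii x 2 regions), plus 4 composite features flagged
# "reconciliation" which close the gap between the per-category counts
# (242) and the 246-feature total.

HARALICK_NAMES <- c("asm", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy", "entropy",
                    "diff_variance", "diff_entropy", "imc1", "imc2")

HISTOGRAM_NAMES <- c("hist_mean", "hist_sd", "hist_skewness", "hist_kurtosis",
                     "hist_entropy", "hist_p10", "hist_p90")

TEXTURE_NAMES <- c(paste0("glcm1_", HARALICK_NAMES),
                   paste0("glcm2_", HARALICK_NAMES),
                   "grad_mean", "grad_sd", "grad_skewness", "grad_p90",
                   "grad_otsu_frac")

COLOR_NAMES <- as.vector(t(outer(c("color_r", "color_g", "color_b"),
                                 c("mean", "sd", "skewness", "entropy", "p10",
                                   "median", "p90", "min", "max"), paste,
                                 sep = "_")))

# 75 per-nucleus base descriptors, in extraction order
BASE_DESCRIPTORS <- c(MORPHOLOGY_NAMES, HISTOGRAM_NAMES, TEXTURE_NAMES,
                      COLOR_NAMES)

BASE_CATEGORIES <- rep(c("morphology", "histogram", "texture", "color"),
                       c(10, 7, 31, 27))

DH_STATS <- c("density", "quadrat_mean", "quadrat_sd", "quadrat_cv",
              "quadrat_frac_empty", "morisita", "nn_dist")

INTERACTION_STATS <- c("mean", "sd", "median", "max", "skewness", "q75",
                       "frac_zero", "entropy")

REGION_CODES <- c(TUMOR_CORE = "CT", TUMOR_PERIPHERY = "PT")

nuclei_feature_names <- function() {
  as.vector(t(outer(paste0("tumor_", BASE_DESCRIPTORS), c("mean", "sd"),
                    paste, sep = "_")))
}

dh_feature_names <- function() {
  out <- character(0)
  for (reg in c("CT", "PT"))
    for (cls in c("tumor", "lymph"))
      out <- c(out, paste0(cls, "_", DH_STATS, "_", reg))
  out
}

interaction_feature_names <- function() {
  out <- character(0)
  for (reg in c("CT", "PT"))
    for (r in c(50, 100))
      for (cls in c("tumor", "lymph"))
        out <- c(out, paste0("tumor_", cls, "_relation_", INTERACTION_STATS,
                             if (r == 100) "_r100" else "", "_", reg))
  out
}

composite_feature_names <- function() {
  c("lymph_tumor_ratio_CT", "total_count_CT",
    "lymph_tumor_ratio_PT", "total_count_PT")
}

#' The feature registry
#'
#' Machine-readable registry of all 246 patient-level features in extraction
#' order: name, category, tissue region, radius (interaction features only)
#' and a short formula note. Radius-50 interaction features carry unsuffixed
#' names (e.g. `tumor_lymph_relation_mean_CT`, the mean lymphocyte count
#' within 50 px of each tumor cell in the tumor core); radius-100 features
#' carry an `_r100` suffix.
#'
#' @return data.frame with 246 rows and columns `name`, `category`,
#'   `region`, `radius`, `formula`.
#' @export
feature_registry <- function() {
  nuc <- data.frame(
    name = nuclei_feature_names(),
    category = rep(BASE_CATEGORIES, each = 2),
    region = "WHOLE_TUMOR", radius = NA_real_,
    formula = paste0(rep(BASE_DESCRIPTORS, each = 2), ":",
                     rep(c("mean", "sd"), 75), " over tumor nuclei"))
  dh <- data.frame(
    name = dh_feature_names(),
    category = "density_homogeneity",
    region = rep(names(REGION_CODES), each = 14), radius = NA_real_,
    formula = paste0(rep(rep(DH_STATS, 2), 2), " of ",
                     rep(rep(c("tumor", "lymphocyte"), each = 7), 2),
                     " point pattern (200 px quadrats)"))
  inter <- data.frame(
    name = interaction_feature_names(),
    category = "interaction",
    region = rep(names(REGION_CODES), each = 32),
    radius = rep(rep(c(50, 100), each = 16), 2),
    formula = paste0(rep(rep(rep(INTERACTION_STATS, 2), 2), 2),
                     " of per-tumor-cell ",
                     rep(rep(rep(c("tumor", "lymphocyte"), each = 8), 2), 2),
                     " neighbor counts"))
  comp <- data.frame(
    name = composite_feature_names(),
    category = "composite",
    region = rep(names(REGION_CODES), each = 2), radius = NA_real_,
    formula = rep(c("lymphocyte:tumor count ratio (reconciliation)",
                    "total nuclei count (reconciliation)"), 2))
  rbind(nuc, dh, inter, comp)
}

#' All 246 feature names in extraction order
#' @return character vector of length 246.
#' @export
feature_names <- function() feature_registry()$name

#' Write the feature registry as TSV
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_registry <- function(path) {
  write.table(feature_registry(), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
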