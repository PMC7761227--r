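# End-to-end orchestration: extract -> cluster -> (igp) -> stats ->
# survival, with every stage runnable standalone and all outputs
# reproducible from the run manifest.

#' Run the full analysis pipeline on a cohort
#'
#' Executes feature extraction, consensus clustering with delta-area K
#' selection, optionally an in-group-proportion reproducibility check on a
#' seeded discovery/validation split, feature-subtype association tests,
#' and the survival stage (Kaplan-Meier + log-rank across subtypes,
#' multivariable Cox). Stages degrade gracefully: without a clinical
#' table the statistical stages are skipped with a warning.
#'
#' @param cohort a [simulate_cohort()] / [read_cohort()] style list
#'   (`maps`, `images` or `image_of`, optional `clinical`), or a cohort
#'   directory path.
#' @param out_dir output directory for CSV/JSON artifacts (NULL = return
#'   results only).
#' @param k_range candidate cluster numbers.
#' @param B consensus replicates.
#' @param p_feature feature resampling fraction.
#' @param seed seed for clustering (and the discovery split).
#' @param discovery_frac if non-NULL, fraction of specimens assigned to a
#'   random discovery set; clustering runs on it and IGP measures
#'   reproducibility in the complement.
#' @param quadrat_side,radii feature-extraction parameters.
#' @param baselines Cox baselines (subtype / stage / grade / sex).
#' @return list with `features`, `consensus`, `labels`, `igp`,
#'   `association`, `survival`, `manifest`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, k_range = 2:6, B = 1000,
                         p_feature = 0.8, seed = 1, discovery_frac = NULL,
                         quadrat_side = 200, radii = c(50, 100),
                         baselines = list(subtype = "1", stage = "pT1",
                                          grade = "G1", sex = "female")) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  images <- cohort$images
  if (is.null(images)) images <- cohort$image_of
  if (is.null(images))
    stop("cohort provides neither images nor an image_of loader")

  features <- extract_cohort(cohort$maps, images,
                             quadrat_side = quadrat_side, radii = radii)
  fm <- feature_matrix(features, quiet = TRUE)

  igp_res <- NULL
  if (!is.null(discovery_frac)) {
    set.seed(seed)
    n <- nrow(features)
    disc <- sort(sample.int(n, round(discovery_frac * n)))
    cc <- consensus_cluster(features[disc, , drop = FALSE], k_range, B,
                            p_feature, seed = seed)
    labels <- setNames(rep(NA_integer_, n), rownames(features))
    labels[disc] <- cc$labels[[as.character(cc$optimal_k)]]
    igp_res <- igp(features[disc, , drop = FALSE],
                   cc$labels[[as.character(cc$optimal_k)]],
                   features[-disc, , drop = FALSE], seed = seed)
    labels[-disc] <- igp_res$assignment
  } else {
    cc <- consensus_cluster(features, k_range, B, p_feature, seed = seed)
    labels <- setNames(cc$labels[[as.character(cc$optimal_k)]],
                       rownames(features))
  }

  association <- feature_subtype_tests(features, labels)

  surv_res <- NULL
  if (!is.null(cohort$clinical)) {
    cl <- cohort$clinical
    cl <- cl[match(rownames(features), cl$specimen_id), ]
    cl$subtype <- as.character(labels)
    km <- km_logrank(cl, cl$subtype)
    cox <- tryCatch(
      cox_ph(cl, c("subtype", "stage", "grade", "sex"), baselines),
      error = function(e) {
        warning("Cox stage skipped: ", conditionMessage(e))
        NULL
      })
    surv_res <- list(km = km, cox = cox)
  } else {
    warning("no clinical table; stats/survival stages limited")
  }

  manifest <- list(k_range = k_range, B = B, p_feature = p_feature,
                   seed = seed, discovery_frac = discovery_frac,
                   quadrat_side = quadrat_side, radii = radii,
                   optimal_k = cc$optimal_k, n_specimens = nrow(features),
                   package_version = as.character(utils::packageVersion("hespat")))

  res <- list(features = features, consensus = cc, labels = labels,
              igp = igp_res, association = association,
              survival = surv_res, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(specimen_id = rownames(res$features), res$features,
                       check.names = FALSE),
            file.path(out_dir, "features.csv"), row.names = FALSE)
  write_feature_registry(file.path(out_dir, "feature_registry.tsv"))
  cc <- res$consensus
  write.csv(data.frame(K = cc$k_range, A = cc$A, delta = cc$delta),
            file.path(out_dir, "consensus_cdf.csv"), row.names = FALSE)
  for (k in names(cc$consensus))
    write.csv(cc$consensus[[k]],
              file.path(out_dir, paste0("consensus_K", k, ".csv")))
  write.csv(data.frame(specimen_id = names(res$labels),
                       subtype = res$labels),
            file.path(out_dir, "labels.csv"), row.names = FALSE)
  write.csv(res$association, file.path(out_dir, "association.csv"),
            row.names = FALSE)
  if (!is.null(res$igp))
    write.csv(data.frame(cluster = names(res$igp$igp), igp = res$igp$igp,
                         p = res$igp$p_value),
              file.path(out_dir, "igp.csv"), row.names = FALSE)
  if (!is.null(res$survival)) {
    write.csv(res$survival$km$km, file.path(out_dir, "km_curves.csv"),
              row.names = FALSE)
    if (!is.null(res$survival$cox))
      write.csv(res$survival$cox, file.path(out_dir, "cox.csv"),
                row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
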