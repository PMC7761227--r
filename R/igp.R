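# Cluster reproducibility across cohorts: the in-group proportion (IGP)
# statistic with a label-permutation null.

row_spearman_dist <- function(a, b) 1 - cor(rank(a), rank(b))

#' In-group proportion of discovery clusters in a validation cohort
#'
#' Discovery centroids (feature-wise means per cluster) classify each
#' validation specimen to its nearest centroid under the Spearman
#' distance. IGP(g) is the proportion of validation specimens classified
#' to g whose nearest validation neighbor (same distance) is also
#' classified to g. Significance comes from a label-permutation null: the
#' classified validation labels are shuffled `n_perm` times and
#' p(g) = (1 + #\{IGP_perm(g) >= IGP_obs(g)\}) / (n_perm + 1).
#'
#' @param X_disc discovery specimens x features matrix (or
#'   [feature_matrix()]).
#' @param labels_disc discovery cluster labels (each cluster >= 2 members).
#' @param X_val validation matrix over the same features.
#' @param n_perm permutations for the null (default 1000).
#' @param seed RNG seed for the permutations.
#' @return object of class `igp_result`: per-cluster `igp`, permutation
#'   `p_value`, and the `assignment` of validation specimens.
#' @export
igp <- function(X_disc, labels_disc, X_val, n_perm = 1000, seed = 1) {
  X_disc <- unclass(as_feature_matrix(X_disc))
  X_val <- unclass(as_feature_matrix(X_val))
  stopifnot(ncol(X_disc) == ncol(X_val))
  labels_disc <- as.integer(factor(labels_disc))
  if (any(table(labels_disc) < 2))
    stop("every discovery cluster needs at least 2 members")
  groups <- sort(unique(labels_disc))

  centroids <- t(vapply(groups, function(g)
    colMeans(X_disc[labels_disc == g, , drop = FALSE]), numeric(ncol(X_disc))))

  nv <- nrow(X_val)
  dcent <- vapply(seq_len(nv), function(i)
    vapply(seq_len(nrow(centroids)), function(g)
      row_spearman_dist(X_val[i, ], centroids[g, ]), 0), numeric(length(groups)))
  assignment <- groups[apply(dcent, 2, which.min)]

  dval <- spearman_distance(X_val)
  diag(dval) <- Inf
  nn <- apply(dval, 1, which.min)

  igp_of <- function(lab) {
    vapply(groups, function(g) {
      members <- which(lab == g)
      if (length(members) == 0) return(NA_real_)
      mean(lab[nn[members]] == g)
    }, 0)
  }
  observed <- igp_of(assignment)
  if (any(is.na(observed)))
    message("empty classified group(s): ",
            paste(groups[is.na(observed)], collapse = ", "))

  set.seed(seed)
  exceed <- rep(0, length(groups))
  for (b in seq_len(n_perm)) {
    perm <- igp_of(sample(assignment))
    exceed <- exceed + (!is.na(perm) & !is.na(observed) & perm >= observed)
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[is.na(observed)] <- NA_real_

  structure(list(igp = setNames(observed, groups),
                 p_value = setNames(p, groups),
                 assignment = setNames(assignment, rownames(X_val)),
                 n_perm = n_perm),
            class = "igp_result")
}

#' @export
print.igp_result <- function(x, ...) {
  cat("<igp_result>\n")
  for (g in names(x$igp))
    cat(sprintf("  cluster %s: IGP = %.3f, p = %.4g\n",
                g, x$igp[g], x$p_value[g]))
  invisible(x)
}

#' Match clusters between two cohorts by centroid correlation
#'
#' Greedy one-to-one matching of cluster centroids by maximal Spearman
#' correlation; used to align independently discovered subtype labels
#' before comparing them.
#'
#' @param X_a,labels_a first cohort matrix and labels.
#' @param X_b,labels_b second cohort matrix and labels.
#' @return data.frame with columns `cluster_a`, `cluster_b`, `rho`.
#' @export
match_clusters <- function(X_a, labels_a, X_b, labels_b) {
  X_a <- unclass(as_feature_matrix(X_a))
  X_b <- unclass(as_feature_matrix(X_b))
  ga <- sort(unique(labels_a)); gb <- sort(unique(labels_b))
  ca <- t(vapply(ga, function(g)
    colMeans(X_a[labels_a == g, , drop = FALSE]), numeric(ncol(X_a))))
  cb <- t(vapply(gb, function(g)
    colMeans(X_b[labels_b == g, , drop = FALSE]), numeric(ncol(X_b))))
  rho <- matrix(NA_real_, length(ga), length(gb))
  for (i in seq_along(ga)) for (j in seq_along(gb))
    rho[i, j] <- cor(rank(ca[i, ]), rank(cb[j, ]))
  out <- data.frame()
  used <- logical(length(gb))
  for (i in order(apply(rho, 1, max, na.rm = TRUE), decreasing = TRUE)) {
    j <- order(replace(rho[i, ], used, -Inf), decreasing = TRUE)[1]
    used[j] <- TRUE
    out <- rbind(out, data.frame(cluster_a = ga[i], cluster_b = gb[j],
                                 rho = rho[i, j]))
  }
  out[order(out$cluster_a), ]
}
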