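# Downstream association and survival stage: feature-subtype tests with
# Benjamini-Hochberg correction, categorical association, correlation,
# Kaplan-Meier / log-rank, and multivariable Cox regression (Breslow ties).

#' Feature-subtype association tests
#'
#' One-way ANOVA (equal-variance F) and Kruskal-Wallis (midrank ties) per
#' feature across subtype groups, each corrected across features with the
#' Benjamini-Hochberg step-up procedure. Features constant across all
#' specimens are reported with the p = 1 convention and flagged.
#'
#' @param X specimens x features matrix (raw values).
#' @param labels group labels (>= 2 groups, each >= 2 members).
#' @return data.frame with columns `feature`, `anova_F`, `anova_p`,
#'   `anova_q`, `kw_H`, `kw_p`, `kw_q`, `note`.
#' @export
feature_subtype_tests <- function(X, labels) {
  X <- as.matrix(X)
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 members")
  res <- lapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    ok <- !is.na(v)
    if (sum(ok) < 3 || length(unique(v[ok])) == 1)
      return(data.frame(anova_F = NA_real_, anova_p = 1, kw_H = NA_real_,
                        kw_p = 1, note = "constant"))
    a <- tryCatch(oneway.test(v[ok] ~ g[ok], var.equal = TRUE),
                  error = function(e) NULL)
    k <- tryCatch(kruskal.test(v[ok], g[ok]), error = function(e) NULL)
    data.frame(
      anova_F = if (is.null(a)) NA_real_ else unname(a$statistic),
      anova_p = if (is.null(a) || is.na(a$p.value)) 1 else a$p.value,
      kw_H = if (is.null(k)) NA_real_ else unname(k$statistic),
      kw_p = if (is.null(k) || is.na(k$p.value)) 1 else k$p.value,
      note = "")
  })
  out <- do.call(rbind, res)
  out <- cbind(feature = colnames(X) %||% as.character(seq_len(ncol(X))), out)
  out$anova_q <- p.adjust(out$anova_p, method = "BH")
  out$kw_q <- p.adjust(out$kw_p, method = "BH")
  out[, c("feature", "anova_F", "anova_p", "anova_q", "kw_H", "kw_p",
          "kw_q", "note")]
}

#' Chi-squared association test for a contingency table
#'
#' Pearson chi-squared with expected counts from the margins. Yates
#' continuity correction is applied iff the table is 2 x 2 and `yates` is
#' TRUE (the default for 2 x 2 tables). Rows/columns labelled "unknown"
#' should be dropped by the caller (see [crosstab()]).
#'
#' @param tab r x c count matrix (r, c >= 2; no zero margins).
#' @param yates apply the continuity correction (2 x 2 only)?
#' @return data.frame with `statistic`, `df`, `p`.
#' @export
chisq_association <- function(tab, yates = NULL) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  is2x2 <- nrow(tab) == 2 && ncol(tab) == 2
  if (is.null(yates)) yates <- is2x2
  ct <- suppressWarnings(chisq.test(tab, correct = yates && is2x2))
  data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value)
}

#' Cross-tabulate two categorical variables, dropping "unknown"
#'
#' @param a,b categorical vectors.
#' @param drop values treated as missing (default `"unknown"` and NA).
#' @return contingency matrix.
#' @export
crosstab <- function(a, b, drop = "unknown") {
  keep <- !(a %in% drop) & !(b %in% drop) & !is.na(a) & !is.na(b)
  table(droplevels(factor(a[keep])), droplevels(factor(b[keep])))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance).
#' @return data.frame with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) stop("zero variance input")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Kaplan-Meier estimates and log-rank test across groups
#'
#' Product-limit estimator per group and the log-rank chi-squared with
#' groups - 1 degrees of freedom.
#'
#' @param clinical data.frame with `os_time` and `os_event`.
#' @param groups group label per row (>= 2 nonempty groups; >= 1 event
#'   overall).
#' @return list with `km` (step table: group, time, n_risk, n_event,
#'   surv), `statistic`, `df`, `p`.
#' @export
km_logrank <- function(clinical, groups) {
  g <- factor(groups)
  if (any(table(g) == 0) || nlevels(g) < 2)
    stop("need at least 2 nonempty groups")
  if (sum(clinical$os_event) < 1) stop("need at least one event")
  s <- survival::Surv(clinical$os_time, clinical$os_event)
  fit <- survival::survfit(s ~ g)
  sm <- summary(fit)
  km <- data.frame(group = sub("^g=", "", as.character(sm$strata)),
                   time = sm$time, n_risk = sm$n.risk,
                   n_event = sm$n.event, surv = sm$surv)
  lr <- survival::survdiff(s ~ g)
  df <- length(lr$n) - 1
  list(km = km, statistic = unname(lr$chisq), df = df,
       p = stats::pchisq(lr$chisq, df, lower.tail = FALSE))
}

#' Multivariable Cox proportional-hazards model
#'
#' Partial-likelihood Newton-Raphson fit with Breslow tie handling
#' (Efron available via `ties`). Categorical covariates are dummy-coded
#' against the stated baseline levels; the returned table has one row per
#' non-baseline level with log-HR, HR, Wald 95% CI exp(beta +/- 1.96 se)
#' and Wald p.
#'
#' @param clinical data.frame with `os_time`, `os_event` and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param baselines named list of baseline levels for categorical
#'   covariates, e.g. `list(subtype = "1", stage = "pT1", grade = "G1",
#'   sex = "female")`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame with `term`, `beta`, `se`, `HR`, `lo95`, `hi95`,
#'   `p`.
#' @export
cox_ph <- function(clinical, covariates, baselines = list(),
                   ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  dat <- clinical[, c("os_time", "os_event", covariates), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  for (v in covariates) {
    if (is.character(dat[[v]]) || is.factor(dat[[v]])) {
      dat <- dat[!(dat[[v]] %in% "unknown"), , drop = FALSE]
      dat[[v]] <- factor(dat[[v]])
      if (!is.null(baselines[[v]]))
        dat[[v]] <- stats::relevel(dat[[v]], ref = baselines[[v]])
    }
  }
  n_par <- sum(vapply(covariates, function(v)
    if (is.factor(dat[[v]])) nlevels(dat[[v]]) - 1L else 1L, 0L))
  if (sum(dat$os_event) < n_par)
    stop("fewer events (", sum(dat$os_event), ") than parameters (",
         n_par, ")")
  fml <- stats::as.formula(paste("survival::Surv(os_time, os_event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  if (fit$iter >= 100)
    stop("Cox model did not converge in 100 iterations")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  data.frame(term = names(beta), beta = unname(beta), se = unname(se),
             HR = exp(unname(beta)),
             lo95 = exp(unname(beta) - 1.96 * unname(se)),
             hi95 = exp(unname(beta) + 1.96 * unname(se)),
             p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))))
}
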