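# Random-intercept linear mixed models for longitudinal expression.
#
# The model is y = X beta + b[patient] + eps with b ~ N(0, sigma_b^2) and
# eps ~ N(0, sigma_e^2). For a single random intercept the likelihood
# profiles down to a one-dimensional problem in the variance ratio
# lambda = sigma_b^2 / sigma_e^2: given lambda, GLS reduces to OLS on
# within-patient partially centered data (y - theta_d * ybar_d with
# theta_d = 1 - 1/sqrt(1 + n_d * lambda)), and sigma_e^2 has a closed form.

# Precompute grouping structure for repeated fits on the same design.
lmm_groups <- function(groups) {
  g <- as.integer(factor(groups))
  list(g = g, n_d = tabulate(g), n_groups = max(g))
}

# Partially center y (vector or matrix columns) by group, given theta per group.
partial_center <- function(x, gi, theta) {
  if (is.matrix(x)) {
    means <- rowsum(x, gi$g) / gi$n_d
    x - theta[gi$g] * means[gi$g, , drop = FALSE]
  } else {
    means <- rowsum(x, gi$g)[, 1] / gi$n_d
    x - theta[gi$g] * means[gi$g]
  }
}

# -2 * profiled (restricted) log-likelihood at variance ratio lambda.
lmm_deviance <- function(lambda, y, X, gi, reml) {
  n <- length(y)
  p <- ncol(X)
  theta <- 1 - 1 / sqrt(1 + gi$n_d * lambda)
  yt <- partial_center(y, gi, theta)
  Xt <- partial_center(X, gi, theta)
  fit <- stats::lm.fit(Xt, yt)
  rss <- sum(fit$residuals^2)
  ldet <- sum(log1p(gi$n_d * lambda))
  if (reml) {
    XtX <- crossprod(Xt)
    (n - p) * log(2 * pi * rss / (n - p)) + ldet +
      determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p)
  } else {
    n * log(2 * pi * rss / n) + ldet + n
  }
}

#' Fit a single-random-intercept linear mixed model
#'
#' Estimates fixed effects, the patient random-intercept variance and the
#' residual variance by one-dimensional optimization of the profiled
#' (restricted) log-likelihood over the variance ratio, with closed-form
#' generalized-least-squares fixed effects at each candidate ratio.
#'
#' @param y numeric response vector (one feature across samples).
#' @param design numeric fixed-effect design matrix including the intercept.
#' @param groups per-sample grouping factor (patient ids).
#' @param criterion "ML" (needed for likelihood-ratio tests) or "REML".
#' @return object of class `lmm_fit` with elements `fixed_effects`,
#'   `se`, `t_statistic`, `random_intercept_variance`, `residual_variance`,
#'   `log_likelihood` (at the chosen criterion), `criterion`, `n_obs`,
#'   `n_groups`, `converged`.
#' @export
fit_lmm <- function(y, design, groups, criterion = c("ML", "REML")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X) || length(groups) != nrow(X))
    stop("y, design and groups must have matching length")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  gi <- lmm_groups(groups)
  if (gi$n_groups < 2) stop("need >= 2 groups (patients)")
  reml <- criterion == "REML"

  dev <- function(loglam) lmm_deviance(exp(loglam), y, X, gi, reml)
  opt <- stats::optimize(dev, interval = c(log(1e-8), log(1e8)), tol = 1e-8)
  dev0 <- lmm_deviance(0, y, X, gi, reml)
  lambda <- if (dev0 <= opt$objective) 0 else exp(opt$minimum)
  # treat tiny ratios as the boundary
  if (lambda < 1e-7) lambda <- 0

  n <- length(y)
  p <- ncol(X)
  theta <- 1 - 1 / sqrt(1 + gi$n_d * lambda)
  yt <- partial_center(y, gi, theta)
  Xt <- partial_center(X, gi, theta)
  fit <- stats::lm.fit(Xt, yt)
  rss <- sum(fit$residuals^2)
  sigma_e2 <- if (reml) rss / (n - p) else rss / n
  beta <- fit$coefficients
  XtXinv <- chol2inv(chol(crossprod(Xt)))
  se <- sqrt(diag(XtXinv) * sigma_e2)
  names(se) <- colnames(X)
  ll <- -0.5 * lmm_deviance(lambda, y, X, gi, reml)
  structure(list(fixed_effects = stats::setNames(beta, colnames(X)),
                 se = se, t_statistic = beta / se,
                 random_intercept_variance = lambda * sigma_e2,
                 residual_variance = sigma_e2,
                 log_likelihood = ll, criterion = criterion,
                 n_obs = n, n_groups = gi$n_groups, converged = TRUE),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (", x$criterion, "), ", x$n_obs, " obs / ",
      x$n_groups, " groups\n", sep = "")
  print(round(x$fixed_effects, 4))
  cat("sigma_b^2 =", signif(x$random_intercept_variance, 4),
      " sigma_e^2 =", signif(x$residual_variance, 4),
      " logLik =", signif(x$log_likelihood, 6), "\n")
  invisible(x)
}

#' Likelihood-ratio test for the treatment-time term
#'
#' Compares nested ML fits; the chi-squared statistic is twice the
#' log-likelihood gain, floored at zero.
#'
#' @param full,reduced `lmm_fit` objects fit by ML on identical observations;
#'   `reduced` must be nested in `full`.
#' @return list `chisq`, `df`, `p_value`.
#' @export
lrt_time <- function(full, reduced) {
  if (full$criterion != "ML" || reduced$criterion != "ML")
    stop("likelihood-ratio test requires ML fits")
  if (full$n_obs != reduced$n_obs)
    stop("fits are not on identical observations")
  df <- length(full$fixed_effects) - length(reduced$fixed_effects)
  if (df < 0) stop("reduced model has more fixed effects than full model")
  if (!all(names(reduced$fixed_effects) %in% names(full$fixed_effects)))
    stop("designs are not nested")
  chisq <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p_value = p)
}

# Fixed-effect design for one pairwise time comparison.
# Returns full and reduced model matrices plus the name of the time column.
de_design <- function(clin, time_a, time_b, with_subtype) {
  X <- cbind(`(Intercept)` = 1, purity = clin$purity)
  if (with_subtype) {
    for (s in setdiff(unique(clin$subtype), SUBTYPES[1]))
      X <- cbind(X, as.numeric(clin$subtype == s))
    colnames(X)[(ncol(X) - length(setdiff(unique(clin$subtype), SUBTYPES[1])) + 1):ncol(X)] <-
      paste0("subtype", setdiff(unique(clin$subtype), SUBTYPES[1]))
  }
  tcol <- as.numeric(clin$time == time_b)
  full <- cbind(X, time = tcol)
  list(full = full, reduced = X)
}

#' Pairwise differential expression over treatment time
#'
#' For each pairwise time comparison, fits per feature the random-intercept
#' model on samples at the two time points (purity always a covariate,
#' subtype a covariate only in the overall group) and tests the time term by
#' likelihood ratio. Fold changes are reported on the scale of the input
#' matrix (log2 input gives log2 fold change). FDR is Benjamini-Hochberg
#' within each comparison x group.
#'
#' @param expr log-scale feature matrix (features x samples).
#' @param clinical clinical table covering the matrix columns.
#' @param comparisons list of time pairs, default all three.
#' @param groups "overall", "per-subtype", or both.
#' @param min_patients minimum patients for a subtype group to be analyzed.
#' @return data.frame feature, group, comparison, estimate, t_statistic,
#'   lrt_chisq, p_value, fdr.
#' @export
run_de <- function(expr, clinical,
                   comparisons = list(c("T1", "T2"), c("T2", "T3"),
                                      c("T1", "T3")),
                   groups = "overall", min_patients = 3) {
  validate_clinical(clinical)
  clinical <- clinical[match(colnames(expr), clinical$sample_id), ]
  if (any(is.na(clinical$sample_id)))
    stop("expression columns missing from clinical table")
  group_defs <- list()
  if ("overall" %in% groups)
    group_defs[["overall"]] <- rep(TRUE, nrow(clinical))
  if ("per-subtype" %in% groups)
    for (s in unique(clinical$subtype))
      group_defs[[s]] <- clinical$subtype == s
  out <- list()
  for (gname in names(group_defs)) {
    sel_g <- group_defs[[gname]]
    with_sub <- gname == "overall" &&
      length(unique(clinical$subtype[sel_g])) > 1
    for (cmp in comparisons) {
      sel <- sel_g & clinical$time %in% cmp
      clin <- clinical[sel, ]
      if (length(unique(clin$patient_id)) < min_patients) {
        warning("group '", gname, "' has < ", min_patients,
                " patients for ", paste(cmp, collapse = "-"), "; skipped")
        next
      }
      if (length(unique(clin$time)) < 2) next
      d <- de_design(clin, cmp[[1]], cmp[[2]], with_sub)
      sub <- expr[, sel, drop = FALSE]
      res <- t(apply(sub, 1, function(y) {
        fit_f <- fit_lmm(y, d$full, clin$patient_id, "ML")
        fit_r <- fit_lmm(y, d$reduced, clin$patient_id, "ML")
        lrt <- lrt_time(fit_f, fit_r)
        c(estimate = unname(fit_f$fixed_effects[["time"]]),
          t_statistic = unname(fit_f$t_statistic[["time"]]),
          lrt_chisq = lrt$chisq, p_value = lrt$p_value)
      }))
      df <- data.frame(feature = rownames(sub), group = gname,
                       comparison = paste(cmp, collapse = "-"),
                       res, row.names = NULL, stringsAsFactors = FALSE)
      df$fdr <- stats::p.adjust(df$p_value, "BH")
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, out)
}

#' Select differentially expressed genes
#'
#' Union of features passing `p_value < p_cut` and `|estimate| > lfc_cut`
#' (absolute fold change > 2 on the linear scale corresponds to
#' `lfc_cut = 1` on log2) in at least one comparison x group.
#'
#' @param results output of [run_de()].
#' @param p_cut p-value threshold, default 0.01.
#' @param lfc_cut absolute log2 fold-change threshold, default 1.
#' @return character vector of selected features.
#' @export
select_de_genes <- function(results, p_cut = 0.01, lfc_cut = 1) {
  hit <- results$p_value < p_cut & abs(results$estimate) > lfc_cut
  sort(unique(results$feature[hit]))
}

# Per-time mean profiles of row-z-scored expression, the clustering features.
time_profile_features <- function(expr, clinical, sample_sel = NULL) {
  if (is.null(sample_sel)) sample_sel <- colnames(expr)
  expr <- expr[, sample_sel, drop = FALSE]
  clin <- clinical[match(colnames(expr), clinical$sample_id), ]
  z <- zscale(expr)
  tps <- intersect(TIMEPOINTS, unique(clin$time))
  feat <- sapply(tps, function(tp)
    rowMeans(z[, clin$time == tp, drop = FALSE]))
  colnames(feat) <- tps
  feat
}

#' K-means consensus clustering of DE genes
#'
#' Genes are clustered on per-time-point mean profiles of row-z-scored
#' expression so that temporal shape, not amplitude, drives the grouping.
#' Each resample subsamples samples, recomputes the profiles, and runs
#' k-means; the consensus matrix is the co-assignment frequency and final
#' labels come from an average-linkage hierarchical cut of 1 - consensus.
#'
#' @param expr expression of the selected genes (genes x samples, log scale).
#' @param clinical clinical table for the columns.
#' @param k number of clusters, default 3.
#' @param n_resamples resampling iterations, default 100.
#' @param subsample_frac fraction of samples per resample, default 0.8.
#' @param seed integer seed.
#' @return object of class `consensus_clusters`: `labels` (gene -> "C1"...),
#'   `consensus` (genes x genes in [0,1]).
#' @export
consensus_kmeans <- function(expr, clinical, k = 3, n_resamples = 100,
                             subsample_frac = 0.8, seed = 1L) {
  if (nrow(expr) < k) stop("fewer genes than clusters")
  set.seed(as.integer(seed))
  ng <- nrow(expr)
  co <- matrix(0, ng, ng)
  ns <- ncol(expr)
  for (r in seq_len(n_resamples)) {
    cols <- sample(ns, max(2, round(subsample_frac * ns)))
    feat <- time_profile_features(expr, clinical, colnames(expr)[cols])
    cl <- stats::kmeans(feat, centers = k, nstart = 10)$cluster
    co <- co + outer(cl, cl, "==")
  }
  consensus <- co / n_resamples
  dimnames(consensus) <- list(rownames(expr), rownames(expr))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  labels <- stats::cutree(hc, k = k)
  labels <- stats::setNames(paste0("C", labels), rownames(expr))
  structure(list(labels = labels, consensus = consensus, k = k),
            class = "consensus_clusters")
}

#' @export
print.consensus_clusters <- function(x, ...) {
  cat("Consensus clustering of", length(x$labels), "genes into", x$k,
      "clusters\n")
  print(table(x$labels))
  invisible(x)
}

#' Map pathways to DE gene clusters
#'
#' A pathway maps to a cluster when it is enriched in that cluster at
#' enrichment FDR < `fdr_enrich` and its signature score is differentially
#' expressed over time at FDR < `fdr_de` in the same sample group for at
#' least one pairwise comparison.
#'
#' @param enrichments data.frame with columns `pathway`, `cluster`, `fdr`.
#' @param signature_de [run_de()] output on a signature-score matrix
#'   (feature = pathway).
#' @param fdr_enrich,fdr_de thresholds, defaults 0.20 and 0.05.
#' @return named character vector pathway -> cluster (unmapped omitted).
#' @export
map_pathways_to_clusters <- function(enrichments, signature_de,
                                     fdr_enrich = 0.20, fdr_de = 0.05) {
  de_ok <- tapply(signature_de$fdr, signature_de$feature,
                  function(f) any(f < fdr_de))
  keep <- enrichments$fdr < fdr_enrich &
    enrichments$pathway %in% names(de_ok)[which(de_ok)]
  stats::setNames(enrichments$cluster[keep], enrichments$pathway[keep])
}
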