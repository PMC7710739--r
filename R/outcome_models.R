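# Association of immune features with pathologic response: single-feature
# regression adjusted for clinical covariates, and feature ranking by
# selection frequency over bootstrapped elastic-net logistic fits.

#' Adjusted association of one feature with an outcome
#'
#' Logistic regression (IRLS via `glm`) for a binary outcome, ordinary
#' linear regression for a continuous one, with all covariates included;
#' returns the feature coefficient and its Wald p-value. Perfect separation
#' in the logistic case is flagged and refit with a small ridge penalty.
#'
#' @param feature per-patient numeric feature.
#' @param outcome binary (2 levels) or continuous response.
#' @param covariates data.frame of adjustment covariates (may be empty).
#' @return list `coefficient`, `p_value`, `model` ("logistic"/"linear"),
#'   `separation` flag.
#' @export
adjusted_association <- function(feature, outcome, covariates = NULL) {
  dat <- data.frame(.y = outcome, .x = feature)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    dat <- cbind(dat, as.data.frame(covariates))
  binary <- is.factor(outcome) || is.character(outcome) ||
    length(unique(outcome)) == 2
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                                collapse = " + ")))
  if (binary) {
    dat$.y <- as.integer(factor(dat$.y)) - 1L
    fit <- suppressWarnings(stats::glm(form, stats::binomial(), dat))
    co <- summary(fit)$coefficients
    if (any(is.na(stats::coef(fit)))) stop("aliased covariates in design")
    mu <- stats::fitted(fit)
    separated <- !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
      abs(stats::coef(fit)[".x"]) > 20
    if (separated) {
      # ridge-penalized refit stabilizes the separated likelihood
      X <- stats::model.matrix(form, dat)
      nll <- function(b) {
        eta <- drop(X %*% b)
        sum(log1p(exp(eta))) - sum(dat$.y * eta) + 0.05 * sum(b[-1]^2)
      }
      opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS")
      coef_x <- opt$par[match(".x", colnames(X))]
      return(list(coefficient = coef_x, p_value = co[".x", 4],
                  model = "logistic", separation = TRUE))
    }
    list(coefficient = co[".x", 1], p_value = co[".x", 4],
         model = "logistic", separation = FALSE)
  } else {
    fit <- stats::lm(form, dat)
    if (any(is.na(stats::coef(fit)))) stop("aliased covariates in design")
    co <- summary(fit)$coefficients
    list(coefficient = co[".x", 1], p_value = co[".x", 4],
         model = "linear", separation = FALSE)
  }
}

#' Elastic-net bootstrap variable usage
#'
#' Resamples patients with replacement, fits an elastic-net logistic path
#' per iteration with the penalty chosen by internal cross-validated
#' deviance, and records which features carry nonzero coefficients at that
#' penalty. Usage is the selection percentage over iterations; features are
#' ranked by descending usage with ties broken by mean absolute
#' coefficient. Iterations in which the resampled outcome is constant are
#' redrawn.
#'
#' @param features patients x features numeric matrix (standardized
#'   internally by `glmnet`).
#' @param outcome binary response (factor/character/0-1).
#' @param n_boot bootstrap iterations, default 10000 at full scale.
#' @param alpha elastic-net mixing parameter, default 0.5.
#' @param nfolds internal cross-validation folds, default 5.
#' @param seed integer seed.
#' @return object of class `variable_usage`: data.frame `feature`,
#'   `usage_pct`, `mean_abs_coef`, `rank`; plus `n_boot`, `alpha`.
#' @export
elasticnet_bootstrap <- function(features, outcome, n_boot = 10000,
                                 alpha = 0.5, nfolds = 5, seed = 1L) {
  X <- as.matrix(features)
  if (n_boot < 100) stop("n_boot must be >= 100")
  y <- as.integer(factor(outcome)) - 1L
  if (length(unique(y)) != 2) stop("outcome must be binary")
  set.seed(as.integer(seed))
  p <- ncol(X)
  sel_count <- stats::setNames(numeric(p), colnames(X))
  coef_sum <- sel_count
  n <- nrow(X)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2 && min(table(y[idx])) >= nfolds) break
    }
    cv <- glmnet::cv.glmnet(X[idx, , drop = FALSE], y[idx],
                            family = "binomial", alpha = alpha,
                            nfolds = nfolds, type.measure = "deviance",
                            penalty.factor = rep(1, p))
    co <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    nz <- co != 0
    sel_count[nz] <- sel_count[nz] + 1
    coef_sum <- coef_sum + abs(co)
  }
  usage <- 100 * sel_count / n_boot
  mean_abs <- coef_sum / n_boot
  ord <- order(-usage, -mean_abs)
  tab <- data.frame(feature = colnames(X)[ord], usage_pct = usage[ord],
                    mean_abs_coef = mean_abs[ord],
                    rank = seq_len(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_boot = n_boot, alpha = alpha),
            class = "variable_usage")
}

#' @export
print.variable_usage <- function(x, ...) {
  cat("Elastic-net bootstrap variable usage (", x$n_boot, " iterations, alpha = ",
      x$alpha, ")\n", sep = "")
  print(utils::head(x$table, 10), digits = 3)
  invisible(x)
}

#' Compare usage between feature groups
#'
#' Two-sided Wilcoxon rank-sum test on usage percentages between two named
#' groups of features (e.g. baseline vs on-treatment features).
#'
#' @param usage `variable_usage` object.
#' @param group_a,group_b character vectors of feature names.
#' @return list `p_value`, `statistic`, `median_a`, `median_b`.
#' @export
compare_usage_groups <- function(usage, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be nonempty")
  tab <- usage$table
  ua <- tab$usage_pct[tab$feature %in% group_a]
  ub <- tab$usage_pct[tab$feature %in% group_b]
  if (!length(ua) || !length(ub)) stop("group features not found in usage table")
  wt <- suppressWarnings(stats::wilcox.test(ua, ub, exact = FALSE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_a = stats::median(ua), median_b = stats::median(ub))
}
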