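# Integrative clustering of multiple feature blocks (e.g. immune signature
# scores and immune cell fractions) via a Gaussian latent-variable model:
# x_i = W z_i + e_i with z_i ~ N(0, I_{k-1}) and diagonal noise, fit by EM
# with lasso-type soft-threshold shrinkage of the loadings. Samples are
# assigned to k clusters by k-means on the posterior latent means.

istate_loglik <- function(S, W, psi, n) {
  p <- nrow(W)
  Sigma <- W %*% t(W) + diag(psi, p)
  ch <- chol(Sigma)
  ldet <- 2 * sum(log(diag(ch)))
  inv <- chol2inv(ch)
  -n / 2 * (p * log(2 * pi) + ldet + sum(inv * S))
}

#' Integrative clustering of multi-block sample features
#'
#' Fits a shared Gaussian latent-variable model across feature blocks with
#' `k - 1` latent dimensions by expectation-maximization, applying a
#' soft-threshold (lasso-type) penalty to the loading matrix at each M-step.
#' Features are standardized internally; cluster assignments come from
#' k-means on the posterior latent coordinates. Deterministic given `seed`.
#'
#' @param blocks list of samples x features matrices sharing row (sample)
#'   ids.
#' @param k number of clusters (>= 2); the latent space has `k - 1`
#'   dimensions.
#' @param penalty soft-threshold applied to standardized loadings,
#'   default 0.2.
#' @param max_iter EM iterations, default 100.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer seed (initialization from leading principal
#'   components; k-means restarts).
#' @return object of class `immune_state_model`: `assignments` (named
#'   integer cluster per sample), `latent` (samples x (k-1)), `loadings`
#'   (features x (k-1)), `bic`, `log_likelihood`, `n_params`, `k`,
#'   `degenerate` flag (all loadings shrunk to zero).
#' @export
integrative_cluster <- function(blocks, k, penalty = 0.2, max_iter = 100,
                                tol = 1e-6, seed = 17L) {
  if (!is.list(blocks)) blocks <- list(blocks)
  ids <- rownames(blocks[[1]])
  if (is.null(ids)) stop("blocks need sample rownames")
  for (b in blocks)
    if (!identical(rownames(b), ids)) stop("blocks must share sample ids")
  X <- do.call(cbind, blocks)
  n <- nrow(X)
  if (k > n) stop("k larger than the number of samples")
  if (k < 2) stop("k must be >= 2")
  X <- scale(X)
  X[!is.finite(X)] <- 0            # constant features carry no signal
  p <- ncol(X)
  q <- k - 1
  S <- crossprod(X) / n

  set.seed(as.integer(seed))
  sv <- svd(X, nu = 0, nv = q)
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(n), q)
  psi <- pmax(diag(S) - rowSums(W^2), 1e-4)

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step (Woodbury, q small)
    WP <- W / psi
    M <- diag(q) + crossprod(W, WP)
    Minv <- solve(M)
    EZ <- X %*% WP %*% Minv                 # n x q posterior means
    EZZ <- n * Minv + crossprod(EZ)         # sum_i E[z z']
    # M-step
    XtEZ <- crossprod(X, EZ)
    W_new <- XtEZ %*% solve(EZZ)
    psi_new <- pmax((colSums(X^2) - rowSums(W_new * XtEZ)) / n, 1e-6)
    W <- W_new
    psi <- psi_new
    ll <- istate_loglik(S, W, psi, n)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  # lasso-type soft threshold on the converged loadings, scaled per latent
  # dimension by its strongest loading; penalty >= 1 collapses the model
  if (penalty > 0) {
    thr <- penalty * apply(abs(W), 2, max)
    W <- sign(W) * pmax(abs(W) - rep(thr, each = p), 0)
    psi <- pmax(diag(S) - rowSums(W^2), 1e-6)
  }
  degenerate <- all(W == 0)
  if (degenerate)
    warning("all loadings shrunk to zero; model is a single degenerate cluster")
  WP <- W / psi
  Minv <- solve(diag(q) + crossprod(W, WP))
  EZ <- X %*% WP %*% Minv
  rownames(EZ) <- ids
  if (degenerate) {
    assignments <- stats::setNames(rep(1L, n), ids)
  } else {
    km <- stats::kmeans(EZ, centers = k, nstart = 25)
    assignments <- stats::setNames(km$cluster, ids)
  }
  ll <- istate_loglik(S, W, psi, n)
  n_params <- sum(W != 0) + p
  structure(list(assignments = assignments, latent = EZ, loadings = W,
                 log_likelihood = ll, n_params = n_params,
                 bic = -2 * ll + n_params * log(n), k = k,
                 penalty = penalty, degenerate = degenerate),
            class = "immune_state_model")
}

#' @export
print.immune_state_model <- function(x, ...) {
  cat("Integrative clustering: k =", x$k, ", BIC =", round(x$bic, 1),
      if (x$degenerate) "(degenerate)" else "", "\n")
  print(table(x$assignments))
  invisible(x)
}

#' Select the number of immune states by BIC
#'
#' Fits [integrative_cluster()] over a range of k and returns the k
#' minimizing `BIC = -2 logLik + n_params log(n)`; ties break toward
#' smaller k.
#'
#' @param blocks as in [integrative_cluster()].
#' @param k_range integer vector of candidate k (each >= 2).
#' @param ... passed to [integrative_cluster()].
#' @return list `k` (selected), `bic` (named vector over the range).
#' @export
select_k_bic <- function(blocks, k_range, ...) {
  if (!length(k_range)) stop("empty k range")
  k_range <- sort(unique(as.integer(k_range)))
  bics <- vapply(k_range, function(k)
    integrative_cluster(blocks, k, ...)$bic, numeric(1))
  names(bics) <- k_range
  list(k = k_range[[which.min(bics)]], bic = bics)
}

#' Label clusters as cold / warm / hot immune states
#'
#' Orders the three clusters by the mean of a per-sample immune intensity
#' summary (e.g. z-scored cytolytic score plus TIL-factor score): lowest
#' mean is cold (C), middle warm (W), highest hot (H).
#'
#' @param model `immune_state_model` with k = 3 (or a named cluster vector).
#' @param immune_score named per-sample numeric summary.
#' @return named character vector sample -> "C"/"W"/"H".
#' @export
label_states <- function(model, immune_score) {
  assignments <- if (inherits(model, "immune_state_model"))
    model$assignments else model
  k <- length(unique(assignments))
  if (k != 3) stop("state labeling requires exactly 3 clusters, got ", k)
  immune_score <- immune_score[names(assignments)]
  if (any(is.na(immune_score))) stop("immune score missing for some samples")
  means <- tapply(immune_score, assignments, mean)
  if (anyDuplicated(means))
    stop("tied cluster means; supply a tiebreak (perturb the score)")
  lab <- c("C", "W", "H")[rank(means)]
  names(lab) <- names(means)
  stats::setNames(unname(lab[as.character(assignments)]), names(assignments))
}

#' Immune-state transition table between two time points
#'
#' Counts state changes over paired samples; pairs with a missing state are
#' skipped with a warning.
#'
#' @param assignments named character vector sample -> state.
#' @param pairs output of [build_pairs()].
#' @param states state vocabulary (ordering of the table), default C/W/H.
#' @return object of class `transition_table`: data.frame `from`, `to`,
#'   `count`, plus `margins` (row sums per from-state).
#' @export
transition_table <- function(assignments, pairs, states = c("C", "W", "H")) {
  sa <- assignments[pairs$sample_a]
  sb <- assignments[pairs$sample_b]
  ok <- !is.na(sa) & !is.na(sb)
  if (any(!ok)) warning(sum(!ok), " pair(s) skipped: missing state")
  sa <- factor(sa[ok], levels = states)
  sb <- factor(sb[ok], levels = states)
  tab <- as.data.frame(table(from = sa, to = sb), stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  margins <- tapply(tab$count, tab$from, sum)[states]
  structure(list(table = tab, margins = margins, states = states),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  m <- matrix(x$table$count, nrow = length(x$states),
              dimnames = list(from = x$states, to = x$states))
  print(m)
  invisible(x)
}

#' Transition percentages per edge
#'
#' Each edge's percentage is its count over the from-state margin, via
#' [percent_of()]; edges with an empty margin are dropped.
#'
#' @param tab `transition_table`.
#' @param decimals passed to [percent_of()].
#' @return data.frame `from`, `to`, `count`, `margin`, `percent`.
#' @export
transition_percentages <- function(tab, decimals = 0) {
  df <- tab$table
  df$margin <- as.numeric(tab$margins[df$from])
  df <- df[df$margin > 0, ]
  df$percent <- percent_of(df$count, df$margin, decimals)
  rownames(df) <- NULL
  df
}

#' Association of a feature with immune states by ANOVA
#'
#' F-test of the state term in a linear model of the feature on purity,
#' subtype, and state.
#'
#' @param feature per-sample numeric values.
#' @param states per-sample state labels (>= 2 distinct).
#' @param purity per-sample tumor purity.
#' @param subtype per-sample subtype (optional; ignored if constant).
#' @return list `p_value`, `f_statistic`, `df`.
#' @export
state_feature_anova <- function(feature, states, purity, subtype = NULL) {
  if (length(unique(states)) < 2) stop("need >= 2 states present")
  dat <- data.frame(y = feature, state = factor(states), purity = purity)
  form_r <- y ~ purity
  if (!is.null(subtype) && length(unique(subtype)) > 1) {
    dat$subtype <- factor(subtype)
    form_r <- y ~ purity + subtype
  }
  form_f <- stats::update(form_r, . ~ . + state)
  fit_f <- stats::lm(form_f, dat)
  if (any(is.na(stats::coef(fit_f)[grep("^state", names(stats::coef(fit_f)))])))
    stop("state term aliased with covariates")
  fit_r <- stats::lm(form_r, dat)
  a <- stats::anova(fit_r, fit_f)
  list(p_value = a$`Pr(>F)`[2], f_statistic = a$F[2],
       df = c(a$Df[2], a$Res.Df[2]))
}
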