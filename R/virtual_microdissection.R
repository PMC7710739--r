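# Non-negative matrix factorization of bulk expression into tissue
# compartment factors, using Kullback-Leibler multiplicative updates
# (the classic "brunet" algorithm), with cophenetic rank selection and
# entropy-based exemplar-gene extraction.

# KL divergence D(V || WH), with the 0 * log 0 convention.
kl_error <- function(V, WH) {
  WH <- pmax(WH, 1e-12)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

nmf_single_run <- function(V, k, max_iter, conn_patience, check_every) {
  g <- nrow(V); s <- ncol(V)
  W <- matrix(stats::runif(g * k, 0.1, 1), g, k)
  H <- matrix(stats::runif(k * s, 0.1, 1), k, s)
  conn_old <- NULL
  stable <- 0L
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, 1e-12)
    H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), 1e-12)
    WH <- pmax(W %*% H, 1e-12)
    W <- W * ((V / WH) %*% t(H)) / pmax(rep(rowSums(H), each = g), 1e-12)
    dim(W) <- c(g, k)
    if (it %% check_every == 0) {
      conn <- apply(H, 2, which.max)
      if (!is.null(conn_old) && identical(conn, conn_old)) {
        stable <- stable + 1L
        if (stable >= conn_patience) break
      } else stable <- 0L
      conn_old <- conn
    }
  }
  list(W = W, H = H, error = kl_error(V, W %*% H), iterations = it)
}

#' Non-negative matrix factorization (KL multiplicative updates)
#'
#' Factorizes a non-negative expression matrix `V` (typically log2(TPM+1))
#' into `W %*% H` with `k` factors using the multiplicative update rules
#' that monotonically decrease the Kullback-Leibler divergence. Each run
#' starts from random non-negative values; a run stops when the sample
#' connectivity (argmax factor per sample) is unchanged for
#' `conn_patience` consecutive checks (every `check_every` iterations) or
#' at `max_iter`. The best of `n_runs` by KL error is returned.
#'
#' @param V non-negative genes x samples matrix; all-zero gene rows are
#'   dropped with a warning.
#' @param k factorization rank, `k < min(dim(V))`.
#' @param n_runs random restarts, default 30.
#' @param max_iter iteration cap per run, default 2000.
#' @param seed integer seed.
#' @param conn_patience,check_every connectivity stopping rule.
#' @return object of class `nmf_model`: `W` (genes x k), `H` (k x samples),
#'   `k`, `error` (KL divergence), `run_errors`, `seed`.
#' @export
nmf_brunet <- function(V, k, n_runs = 30, max_iter = 2000, seed = 1L,
                       conn_patience = 40, check_every = 10) {
  if (any(V < 0)) stop("V must be non-negative")
  if (k >= min(dim(V))) stop("k must be smaller than both dimensions of V")
  zero_rows <- rowSums(V) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " all-zero gene row(s) dropped")
    V <- V[!zero_rows, , drop = FALSE]
  }
  set.seed(as.integer(seed))
  best <- NULL
  run_errors <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    run <- nmf_single_run(V, k, max_iter, conn_patience, check_every)
    run_errors[r] <- run$error
    if (is.null(best) || run$error < best$error) best <- run
  }
  dimnames(best$W) <- list(rownames(V), paste0("F", seq_len(k)))
  dimnames(best$H) <- list(paste0("F", seq_len(k)), colnames(V))
  structure(list(W = best$W, H = best$H, k = k, error = best$error,
                 run_errors = run_errors, seed = as.integer(seed)),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat("NMF model: k =", x$k, ",", nrow(x$W), "genes x", ncol(x$H),
      "samples, KL error =", signif(x$error, 6), "\n")
  invisible(x)
}

#' Rank selection by cophenetic coefficient
#'
#' For each candidate rank, runs the factorization `runs_per_k` times, builds
#' the consensus matrix of sample co-clustering (argmax factor per sample),
#' and computes the cophenetic correlation between the consensus-derived
#' distances (1 - consensus) and the cophenetic distances of their
#' average-linkage dendrogram. Returns the rank maximizing the coefficient.
#'
#' @param V non-negative matrix.
#' @param k_range candidate ranks.
#' @param runs_per_k runs per rank (>= 10), default 15.
#' @param seed integer seed.
#' @param ... passed to [nmf_brunet()] (e.g. `max_iter`).
#' @return list `k` (selected), `coefficients` (named per-k vector).
#' @export
cophenetic_select_k <- function(V, k_range, runs_per_k = 15, seed = 1L, ...) {
  if (runs_per_k < 10) stop("runs_per_k must be >= 10")
  coefs <- numeric(length(k_range))
  names(coefs) <- k_range
  for (i in seq_along(k_range)) {
    k <- k_range[[i]]
    s <- ncol(V)
    co <- matrix(0, s, s)
    for (r in seq_len(runs_per_k)) {
      m <- nmf_brunet(V, k, n_runs = 1,
                      seed = as.integer(seed) + i * 1000L + r, ...)
      cl <- apply(m$H, 2, which.max)
      co <- co + outer(cl, cl, "==")
    }
    consensus <- co / runs_per_k
    d <- stats::as.dist(1 - consensus)
    if (all(d %in% c(0, 1)) && stats::sd(d) == 0) {
      coefs[[i]] <- 1   # degenerate: perfectly stable (or single) clustering
      next
    }
    hc <- stats::hclust(d, method = "average")
    coph <- stats::cophenetic(hc)
    coefs[[i]] <- if (stats::sd(coph) == 0) 1 else stats::cor(coph, d)
  }
  list(k = k_range[[which.max(coefs)]], coefficients = coefs)
}

#' Entropy-based factor-specificity score per gene
#'
#' With `p_f = w_f / sum_f w_f` over a gene's row of the gene-weight matrix,
#' the score is `1 + (1/log2 k) * sum_f p_f log2 p_f`: 1 for a gene loading
#' on a single factor, 0 for a uniform gene.
#'
#' @param W non-negative genes x factors matrix.
#' @return named per-gene score in [0, 1]; all-zero rows are excluded.
#' @export
gene_entropy_scores <- function(W) {
  if (any(W < 0)) stop("W must be non-negative")
  rs <- rowSums(W)
  keep <- rs > 0
  if (any(!keep)) warning(sum(!keep), " all-zero row(s) excluded")
  W <- W[keep, , drop = FALSE]
  p <- W / rowSums(W)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  scores <- 1 + rowSums(plogp) / log2(ncol(W))
  stats::setNames(pmin(pmax(scores, 0), 1), rownames(W))
}

#' Exemplar genes per factor
#'
#' A gene is an exemplar when its entropy score exceeds
#' `median(scores) + 3 * MAD(scores)` (MAD unscaled: median absolute
#' deviation from the median, no normality constant) and the maximum of its
#' row of `W` exceeds the median of all entries of `W`. Each selected gene
#' is assigned to its argmax factor.
#'
#' @param W non-negative genes x factors matrix.
#' @return named list factor -> character vector of gene ids (possibly
#'   empty).
#' @export
exemplar_genes <- function(W) {
  scores <- suppressWarnings(gene_entropy_scores(W))
  med <- stats::median(scores)
  mad_u <- stats::median(abs(scores - med))
  thr <- med + 3 * mad_u
  w_med <- stats::median(W)
  keep <- names(scores)[scores > thr &
                          apply(W[names(scores), , drop = FALSE], 1, max) > w_med]
  factors <- colnames(W)
  if (is.null(factors)) factors <- paste0("F", seq_len(ncol(W)))
  out <- stats::setNames(vector("list", ncol(W)), factors)
  for (f in factors) out[[f]] <- character(0)
  if (length(keep)) {
    assign_f <- factors[apply(W[keep, , drop = FALSE], 1, which.max)]
    for (i in seq_along(keep))
      out[[assign_f[[i]]]] <- c(out[[assign_f[[i]]]], keep[[i]])
  }
  out
}

#' Attribute factors to tissue compartments
#'
#' Rule-based attribution: a factor is assigned to a compartment when the
#' sample group with the highest mean factor weight carries that
#' compartment's label and, if exemplar enrichments are supplied, its
#' exemplar genes enrich a matching pathway category. Factors with
#' conflicting evidence stay unassigned. Composite factors sum the sample
#' weights of their members.
#'
#' @param model `nmf_model`.
#' @param cohort_labels named character vector sample -> compartment label
#'   (e.g. "tumor-intrinsic", "TIL", "stromal", "normal").
#' @param exemplar_enrichments optional named character vector
#'   factor -> enriched compartment category; `NA` means no enrichment.
#' @return object of class `factor_annotation`: `compartment` (per factor),
#'   `composites` (list with `F.Tumor` and `F.Normal` per-sample weights).
#' @export
attribute_factors <- function(model, cohort_labels,
                              exemplar_enrichments = NULL) {
  H <- model$H
  labels <- cohort_labels[colnames(H)]
  if (any(is.na(labels))) stop("cohort labels missing for some samples")
  comp <- character(nrow(H))
  names(comp) <- rownames(H)
  for (f in rownames(H)) {
    grp_means <- tapply(H[f, ], labels, mean)
    top <- names(grp_means)[which.max(grp_means)]
    # require clear dominance of the top group over the runner-up
    srt <- sort(grp_means, decreasing = TRUE)
    dominant <- length(srt) == 1 || srt[[1]] > 1.2 * srt[[2]]
    enr_ok <- TRUE
    if (!is.null(exemplar_enrichments) && f %in% names(exemplar_enrichments)) {
      e <- exemplar_enrichments[[f]]
      enr_ok <- !is.na(e) && identical(e, top)
    }
    comp[[f]] <- if (dominant && enr_ok) top else "unassigned"
  }
  composite <- function(which) {
    members <- names(comp)[comp == which]
    if (!length(members)) return(stats::setNames(rep(0, ncol(H)), colnames(H)))
    colSums(H[members, , drop = FALSE])
  }
  structure(list(compartment = comp,
                 composites = list(F.Tumor = composite("tumor-intrinsic"),
                                   F.Normal = composite("normal"))),
            class = "factor_annotation")
}

#' @export
print.factor_annotation <- function(x, ...) {
  cat("Factor compartment attribution:\n")
  print(x$compartment)
  invisible(x)
}
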