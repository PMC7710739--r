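#' Log-transform a TPM matrix
#'
#' Elementwise `log2(x + 1)`.
#'
#' @param expr non-negative expression matrix.
#' @return matrix of the same shape.
#' @export
log_transform <- function(expr) {
  if (any(expr < 0)) stop("log_transform expects non-negative (TPM) input")
  log2(expr + 1)
}

#' Cytolytic activity (CYT) score
#'
#' Per-sample geometric mean of GZMA and PRF1 expression,
#' `sqrt((GZMA + offset) * (PRF1 + offset))`. The small offset keeps the
#' score defined at zero expression.
#'
#' @param expr expression matrix containing rows for both genes.
#' @param offset non-negative pseudo-value, default 0.01.
#' @param genes the two gene ids, default `c("GZMA", "PRF1")`.
#' @return named per-sample numeric vector.
#' @export
cyt_score <- function(expr, offset = 0.01, genes = c("GZMA", "PRF1")) {
  if (offset < 0) stop("offset must be >= 0")
  for (g in genes)
    if (!g %in% rownames(expr)) stop("gene missing from expression: ", g)
  sqrt((expr[genes[[1]], ] + offset) * (expr[genes[[2]], ] + offset))
}

# Gaussian-kernel ECDF statistic per gene across samples: for gene row x,
# F_j = mean_k Phi((x_j - x_k) / h) with bandwidth h = sd(x)/4. A constant
# gene gets 0.5 everywhere.
kcdf_gaussian <- function(x) {
  h <- stats::sd(x) / 4
  if (!is.finite(h) || h == 0) return(rep(0.5, length(x)))
  vapply(x, function(xj) mean(stats::pnorm((xj - x) / h)), numeric(1))
}

# Weighted KS-like random walk for one sample. ranks: integer rank of each
# gene, 1 = highest kcdf statistic. Weight of a gene is
# |rank - (p + 1)/2| ^ tau (symmetric about the middle rank, so reversing a
# ranking exactly negates the walk). Returns the enrichment score.
gsva_walk <- function(ranks, in_set, tau, max_diff) {
  p <- length(ranks)
  ord <- order(ranks)                       # genes from best to worst rank
  inset_ord <- in_set[ord]
  w <- abs(seq_len(p) - (p + 1) / 2)^tau
  w[!inset_ord] <- 0
  denom_in <- sum(w)
  m <- sum(in_set)
  if (denom_in == 0) return(NA_real_)
  step_in <- cumsum(w) / denom_in
  step_out <- cumsum(!inset_ord) / (p - m)
  nu <- step_in - step_out
  max_pos <- max(0, max(nu))
  max_neg <- max(0, -min(nu))
  if (max_diff) max_pos - max_neg
  else if (max_pos >= max_neg) max_pos else -max_neg
}

#' Single-sample gene-set scores via kernel-ECDF random walk
#'
#' For each gene, a Gaussian-kernel smoothed ECDF across samples (bandwidth
#' sd/4) expresses how high that gene sits in each sample relative to the
#' cohort. Within each sample genes are ranked by this statistic and each
#' gene set is scored by a weighted Kolmogorov-Smirnov-like random walk over
#' the ranking with weight exponent `tau`. With `max_diff` the score is the
#' maximum positive deviation minus the magnitude of the maximum negative
#' deviation; otherwise the single largest-magnitude deviation, signed.
#'
#' @param expr log-scale expression matrix (genes x samples, >= 3 samples).
#' @param sets named list of gene-id vectors.
#' @param tau rank-weight exponent, default 1.
#' @param max_diff score mode, default TRUE.
#' @return sets x samples score matrix; sets with no genes in the matrix get
#'   a row of `NA` with a warning.
#' @export
gsva_scores <- function(expr, sets, tau = 1, max_diff = TRUE) {
  if (ncol(expr) < 3) stop("gsva_scores needs >= 3 samples")
  if (!length(sets)) stop("no gene sets supplied")
  genes <- rownames(expr)
  kc <- t(apply(expr, 1, kcdf_gaussian))
  # rank within each sample, 1 = highest statistic; ties broken by row order
  ranks <- apply(-kc, 2, rank, ties.method = "first")
  rownames(ranks) <- genes
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (s in names(sets)) {
    in_set <- genes %in% sets[[s]]
    if (!any(in_set)) {
      warning("gene set '", s, "' has no genes in the expression matrix")
      next
    }
    if (all(in_set)) {
      warning("gene set '", s, "' covers the whole gene universe; score undefined")
      next
    }
    out[s, ] <- vapply(seq_len(ncol(expr)), function(j)
      gsva_walk(ranks[, j], in_set, tau, max_diff), numeric(1))
  }
  out
}

#' Row-wise z-scaling of a score matrix
#'
#' Centers and scales each row to mean 0 and unit standard deviation
#' (denominator n - 1). Zero-variance rows become all zeros with a warning.
#'
#' @param scores numeric matrix (sets or genes x samples).
#' @return matrix of the same shape.
#' @export
zscale <- function(scores) {
  if (ncol(scores) < 2) stop("zscale needs >= 2 samples")
  sds <- apply(scores, 1, stats::sd)
  mus <- rowMeans(scores)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) warning(sum(flat), " zero-variance row(s) set to 0")
  sds[flat] <- 1
  out <- (scores - mus) / sds
  out[flat, ] <- 0
  out
}

#' Hypergeometric enrichment of a gene cluster in a pathway
#'
#' Upper-tail probability of observing at least the actual overlap between a
#' gene cluster and a pathway within a finite gene universe.
#'
#' @param cluster_genes character vector, subset of `universe`.
#' @param pathway character vector of pathway genes.
#' @param universe character vector of all eligible genes.
#' @return list `p_value`, `overlap`, `expected`.
#' @export
hypergeom_enrichment <- function(cluster_genes, pathway, universe) {
  if (!length(universe)) stop("empty gene universe")
  universe <- unique(universe)
  cluster_genes <- intersect(unique(cluster_genes), universe)
  pathway <- intersect(unique(pathway), universe)
  q <- length(intersect(cluster_genes, pathway))
  m <- length(pathway)
  n <- length(universe) - m
  k <- length(cluster_genes)
  p <- stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
  list(p_value = p, overlap = q, expected = k * m / length(universe))
}
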