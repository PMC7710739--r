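#' nu-SVR immune cell deconvolution
#'
#' Infers relative immune cell fractions in bulk mixtures by nu-support
#' vector regression of each mixture on a cell-type signature matrix
#' (linear kernel). Per sample: restrict to shared genes, z-score the
#' mixture and signature columns jointly, fit for each candidate `nu`,
#' keep the fit minimizing the root-mean-square error between fitted and
#' observed mixture, zero negative coefficients, and normalize the rest to
#' sum to one.
#'
#' @param mixture genes x samples non-negative expression (linear scale).
#' @param signature genes x cell-types signature matrix (>= 2 types).
#' @param nus candidate nu values, default `c(0.25, 0.5, 0.75)`.
#' @return object of class `fraction_estimate`: `fractions`
#'   (samples x types, rows sum to 1), `rmse`, `nu` per sample.
#' @export
nusvr_deconvolve <- function(mixture, signature, nus = c(0.25, 0.5, 0.75)) {
  if (ncol(signature) < 2) stop("signature needs >= 2 cell types")
  shared <- intersect(rownames(mixture), rownames(signature))
  if (!length(shared)) stop("no shared genes between mixture and signature")
  if (length(shared) < nrow(signature) / 2)
    warning("fewer than half of signature genes present in mixture")
  S <- signature[shared, , drop = FALSE]
  M <- mixture[shared, , drop = FALSE]
  # joint z-scoring: signature columns scaled once; each mixture column
  # scaled by its own mean/sd so a positive rescaling of the sample cancels
  Sz <- scale(S)
  n_types <- ncol(S)
  frac <- matrix(0, ncol(M), n_types,
                 dimnames = list(colnames(M), colnames(S)))
  rmse <- numeric(ncol(M))
  nu_used <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    y <- as.numeric(scale(M[, j]))
    best <- NULL
    for (nu in nus) {
      fit <- e1071::svm(x = Sz, y = y, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE)
      pred <- as.numeric(stats::predict(fit, Sz))
      err <- sqrt(mean((pred - y)^2))
      if (is.null(best) || err < best$err)
        best <- list(err = err, fit = fit, nu = nu)
    }
    w <- t(best$fit$coefs) %*% best$fit$SV
    w <- as.numeric(w)
    w[w < 0] <- 0
    if (sum(w) == 0) {
      warning("all coefficients <= 0 for sample ", colnames(M)[j],
              "; returning uniform fractions")
      w <- rep(1, n_types)
    }
    frac[j, ] <- w / sum(w)
    rmse[j] <- best$err
    nu_used[j] <- best$nu
  }
  structure(list(fractions = frac, rmse = rmse, nu = nu_used),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat("Immune cell fraction estimates:", nrow(x$fractions), "samples x",
      ncol(x$fractions), "cell types\n")
  cat("mean fit RMSE:", signif(mean(x$rmse), 3), "\n")
  invisible(x)
}

#' Aggregate cell-type fractions into coarser groups
#'
#' Sums fraction columns according to a source-type -> group mapping; row
#' sums are preserved exactly.
#'
#' @param fractions `fraction_estimate` or samples x types matrix.
#' @param mapping named character vector: names are source types, values the
#'   target groups; must cover every column.
#' @return same class as the input with grouped columns.
#' @export
aggregate_cell_types <- function(fractions, mapping) {
  mat <- if (inherits(fractions, "fraction_estimate")) fractions$fractions
         else as.matrix(fractions)
  missing_types <- setdiff(colnames(mat), names(mapping))
  if (length(missing_types))
    stop("unmapped cell types: ", paste(missing_types, collapse = ", "))
  groups <- unique(unname(mapping[colnames(mat)]))
  out <- sapply(groups, function(g)
    rowSums(mat[, colnames(mat)[mapping[colnames(mat)] == g], drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(mat), groups))
  if (inherits(fractions, "fraction_estimate")) {
    fractions$fractions <- out
    fractions
  } else out
}

#' Default 13-type to 10-group aggregation
#'
#' Merges naive CD4 T with regulatory T, naive with memory B, and monocytes
#' with M0 macrophages, leaving ten groups. The grouping is a configurable
#' convention, not a published table.
#'
#' @return named character vector.
#' @export
default_cell_type_mapping <- function() {
  c(T.CD8 = "T.CD8", T.CD4.naive = "T.CD4.other",
    T.CD4.memory = "T.CD4.memory", T.reg = "T.CD4.other",
    B.naive = "B", B.memory = "B", NK = "NK",
    Mono = "M0", M0 = "M0", M1 = "M1", M2 = "M2", Mast = "Mast", DC = "DC")
}

#' Correlate cell fractions with a per-sample score
#'
#' Spearman rank correlation of each cell-type fraction against a score
#' (e.g. cytolytic activity), with two-sided p-values.
#'
#' @param fractions `fraction_estimate` or samples x types matrix.
#' @param score named per-sample numeric vector.
#' @param method correlation method, default "spearman".
#' @return data.frame `cell_type`, `rho`, `p_value` (NA for constant
#'   columns).
#' @export
correlate_fractions_vs_score <- function(fractions, score,
                                         method = "spearman") {
  mat <- if (inherits(fractions, "fraction_estimate")) fractions$fractions
         else as.matrix(fractions)
  if (nrow(mat) < 5) stop("need >= 5 samples")
  score <- score[rownames(mat)]
  if (any(is.na(score))) stop("score missing for some samples")
  res <- lapply(colnames(mat), function(ct) {
    x <- mat[, ct]
    if (stats::sd(x) == 0 || stats::sd(score) == 0)
      return(data.frame(cell_type = ct, rho = NA_real_, p_value = NA_real_))
    ct_test <- suppressWarnings(
      stats::cor.test(x, score, method = method, exact = FALSE))
    data.frame(cell_type = ct, rho = unname(ct_test$estimate),
               p_value = ct_test$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
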