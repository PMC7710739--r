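# Small fixtures shared across test files; everything is built in code.

# A minimal quiet cohort: no noise, no effects unless asked for.
quiet_config <- function(n_patients = 6, n_genes = 12, seed = 1L, ...) {
  simulation_config(n_patients = n_patients, n_genes = n_genes,
                    signature_blocks = c(immune = 4),
                    effect_sizes = list(immune = list()),
                    random_intercept_sd = 0, residual_sd = 0,
                    pcr_rate = 0, dropout_rule = 0, purity_drop = 0,
                    seed = seed, ...)
}

# Clinical table written out by hand for IO/bookkeeping tests.
toy_clinical <- function() {
  data.frame(
    patient_id = rep(c("P1", "P2", "P3"), times = c(3, 2, 1)),
    sample_id = c("P1_T1", "P1_T2", "P1_T3", "P2_T1", "P2_T2", "P3_T1"),
    subtype = c(rep("TN", 3), rep("ER+/HER2-", 2), "HER2+/ER-"),
    time = c("T1", "T2", "T3", "T1", "T2", "T1"),
    purity = c(0.8, 0.6, 0.5, 0.7, 0.6, 0.9),
    pcr = c(rep("RD", 3), rep("pCR", 2), "RD"),
    stringsAsFactors = FALSE)
}

# Independent, deliberately naive implementation of the kernel-ECDF
# random-walk score, written directly from the definition with plain loops.
# Used as the oracle for gsva_scores.
naive_gsva <- function(expr, set_genes, tau = 1, max_diff = TRUE) {
  p <- nrow(expr); n <- ncol(expr)
  kc <- matrix(0, p, n)
  for (i in seq_len(p)) {
    h <- sd(expr[i, ]) / 4
    for (j in seq_len(n)) {
      if (h == 0) kc[i, j] <- 0.5
      else {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + pnorm((expr[i, j] - expr[i, k]) / h)
        kc[i, j] <- acc / n
      }
    }
  }
  in_set <- rownames(expr) %in% set_genes
  out <- numeric(n)
  for (j in seq_len(n)) {
    r <- rank(-kc[, j], ties.method = "first")
    ord <- order(r)
    nu <- numeric(p)
    denom_in <- 0
    for (pos in seq_len(p))
      if (in_set[ord[pos]]) denom_in <- denom_in + abs(pos - (p + 1) / 2)^tau
    run_in <- 0; run_out <- 0
    for (pos in seq_len(p)) {
      g <- ord[pos]
      if (in_set[g]) run_in <- run_in + abs(pos - (p + 1) / 2)^tau / denom_in
      else run_out <- run_out + 1 / (p - sum(in_set))
      nu[pos] <- run_in - run_out
    }
    mp <- max(0, max(nu)); mn <- max(0, -min(nu))
    out[j] <- if (max_diff) mp - mn else if (mp >= mn) mp else -mn
  }
  out
}

# Adjusted Rand index between two labelings (closed-form pair counting);
# mclust::adjustedRandIndex is used as a second opinion where available.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

# Planted three-block non-negative matrix for NMF tests: `n_marker` marker
# genes per block over a nonspecific background.
planted_nmf_matrix <- function(n_bg = 210, n_marker = 30, n_samp_per = 15,
                               seed = 2) {
  set.seed(seed)
  g <- n_bg + 3 * n_marker
  s <- 3 * n_samp_per
  V <- matrix(runif(g * s, 0.5, 1.5), g, s)
  for (b in 1:3) {
    gr <- ((b - 1) * n_marker + 1):(b * n_marker)
    sr <- ((b - 1) * n_samp_per + 1):(b * n_samp_per)
    V[gr, sr] <- V[gr, sr] + matrix(runif(n_marker * n_samp_per, 3, 5),
                                    n_marker, n_samp_per)
  }
  dimnames(V) <- list(paste0("g", seq_len(g)), paste0("s", seq_len(s)))
  attr(V, "marker_blocks") <-
    lapply(1:3, function(b) paste0("g", ((b - 1) * n_marker + 1):(b * n_marker)))
  V
}

# Three-cluster two-block sample fixture for integrative clustering.
planted_state_blocks <- function(n_per = 20, sep = 5, seed = 9) {
  set.seed(seed)
  n <- 3 * n_per
  g <- rep(1:3, each = n_per)
  mu <- matrix(c(0, 0, sep, 0, 0, sep), 3, 2, byrow = TRUE)
  b1 <- matrix(rnorm(n * 6), n, 6); b1[, 1:2] <- b1[, 1:2] + mu[g, ]
  b2 <- matrix(rnorm(n * 5), n, 5); b2[, 1:2] <- b2[, 1:2] + mu[g, ]
  rownames(b1) <- rownames(b2) <- paste0("s", seq_len(n))
  list(blocks = list(b1, b2), labels = g)
}
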