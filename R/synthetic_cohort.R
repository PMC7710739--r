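#' Simulation configuration for a serial-biopsy cohort
#'
#' Defaults emulate the design of a neoadjuvant chemotherapy cohort: 146
#' patients in four IHC subtypes, biopsies at pre-treatment (T1),
#' on-treatment (T2) and surgery (T3), with patients achieving pathologic
#' complete response (pCR) contributing no surgical sample. Expression is
#' generated on the log2 scale from fixed effects of tumor purity, subtype
#' and time plus a patient random intercept and residual noise, then
#' transformed to TPM-like values via `2^x`.
#'
#' @param n_patients number of patients.
#' @param subtype_proportions named probabilities over the four subtypes;
#'   must sum to 1.
#' @param pcr_rate probability a patient achieves pCR (pCR patients lack T3).
#' @param dropout_rule extra probability a non-pCR patient lacks T3.
#' @param n_genes total genes simulated; must cover all signature blocks.
#' @param signature_blocks named gene counts for coherent blocks (e.g. an
#'   immune block carrying a treatment-time effect).
#' @param effect_sizes list with per-block log2-scale fixed effects; each
#'   element may contain `purity`, `subtype` (named contrasts vs ER+/HER2-),
#'   and `time` (named contrasts vs T1).
#' @param random_intercept_sd patient random-intercept SD, log2 units.
#' @param residual_sd residual SD, log2 units.
#' @param baseline_log2 mean baseline log2 expression.
#' @param purity_shape Beta shape parameters for T1 purity.
#' @param purity_drop mean purity decrease at T2/T3 (on-treatment biopsies
#'   carry relatively more non-tumor tissue).
#' @param seed integer seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 146,
                              subtype_proportions = c("ER+/HER2-" = 0.22,
                                                      "ER+/HER2+" = 0.20,
                                                      "HER2+/ER-" = 0.20,
                                                      "TN" = 0.38),
                              pcr_rate = 0.38,
                              dropout_rule = 0.15,
                              n_genes = 2000,
                              signature_blocks = c(immune = 100,
                                                   cell_cycle = 100,
                                                   emt = 100),
                              effect_sizes = list(
                                immune = list(purity = -2, time = c(T2 = 1, T3 = -0.5)),
                                cell_cycle = list(purity = 2, time = c(T2 = -1, T3 = 0.5)),
                                emt = list(purity = -1, time = c(T2 = 0.8, T3 = -0.3))),
                              random_intercept_sd = 0.5,
                              residual_sd = 0.5,
                              baseline_log2 = 5,
                              purity_shape = c(5, 2),
                              purity_drop = 0.15,
                              seed = 1L) {
  if (abs(sum(subtype_proportions) - 1) > 1e-8)
    stop("subtype proportions must sum to 1")
  if (any(subtype_proportions < 0)) stop("negative subtype proportion")
  if (random_intercept_sd < 0 || residual_sd < 0) stop("sds must be >= 0")
  if (n_genes < sum(signature_blocks))
    stop("n_genes smaller than the sum of signature block sizes")
  if (missing(effect_sizes))    # default effects adapt to custom blocks
    effect_sizes <- effect_sizes[intersect(names(effect_sizes),
                                           names(signature_blocks))]
  if (!all(names(effect_sizes) %in% names(signature_blocks)))
    stop("effect_sizes name unknown blocks")
  structure(list(n_patients = n_patients,
                 subtype_proportions = subtype_proportions,
                 pcr_rate = pcr_rate, dropout_rule = dropout_rule,
                 n_genes = n_genes, signature_blocks = signature_blocks,
                 effect_sizes = effect_sizes,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, baseline_log2 = baseline_log2,
                 purity_shape = purity_shape, purity_drop = purity_drop,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Serial-biopsy simulation config:", x$n_patients, "patients,",
      x$n_genes, "genes,", length(x$signature_blocks), "signature blocks\n")
  cat("  sigma_b =", x$random_intercept_sd, " sigma_e =", x$residual_sd,
      " seed =", x$seed, "\n")
  invisible(x)
}

# Gene-level fixed effects table implied by a config: one row per gene with
# block membership, purity effect, subtype contrasts, time contrasts.
config_gene_effects <- function(config) {
  blocks <- config$signature_blocks
  block_of <- rep("background", config$n_genes)
  idx <- 1L
  for (b in names(blocks)) {
    block_of[idx:(idx + blocks[[b]] - 1L)] <- b
    idx <- idx + blocks[[b]]
  }
  eff <- data.frame(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
                    block = block_of,
                    beta_purity = 0,
                    beta_T2 = 0, beta_T3 = 0,
                    stringsAsFactors = FALSE)
  sub_names <- setdiff(SUBTYPES, SUBTYPES[1])
  for (s in sub_names) eff[[paste0("beta_", s)]] <- 0
  for (b in names(config$effect_sizes)) {
    e <- config$effect_sizes[[b]]
    sel <- eff$block == b
    if (!is.null(e$purity)) eff$beta_purity[sel] <- e$purity
    if (!is.null(e$time)) {
      if ("T2" %in% names(e$time)) eff$beta_T2[sel] <- e$time[["T2"]]
      if ("T3" %in% names(e$time)) eff$beta_T3[sel] <- e$time[["T3"]]
    }
    if (!is.null(e$subtype))
      for (s in intersect(names(e$subtype), sub_names))
        eff[[paste0("beta_", s)]][sel] <- e$subtype[[s]]
  }
  eff
}

#' Simulate a longitudinal serial-biopsy cohort
#'
#' Draws a clinical table (subtype, purity, pCR status, sample availability)
#' and a genes x samples TPM expression matrix from the generative model
#' `log2(x) = beta0 + beta1*purity + beta2*subtype + beta3*time + b_patient +
#' eps`, with patient random intercepts `b ~ N(0, sigma_b^2)` and residuals
#' `eps ~ N(0, sigma_e^2)`. pCR patients never receive a T3 sample.
#'
#' @param config a [simulation_config()].
#' @return list with `expression` (TPM matrix), `clinical` (data.frame), and
#'   `truth` (gene effects, genes x patients random-intercept matrix, and
#'   the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  subtype <- sample(names(config$subtype_proportions), n, replace = TRUE,
                    prob = config$subtype_proportions)
  pcr <- ifelse(stats::runif(n) < config$pcr_rate, "pCR", "RD")
  has_t3 <- pcr == "RD" & stats::runif(n) >= config$dropout_rule

  rows <- list()
  for (i in seq_len(n)) {
    tps <- c("T1", "T2", if (has_t3[[i]]) "T3")
    for (tp in tps)
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = patients[[i]],
                   sample_id = paste0(patients[[i]], "_", tp),
                   subtype = subtype[[i]], time = tp, purity = NA_real_,
                   pcr = pcr[[i]], stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, rows)
  base_purity <- stats::rbeta(n, config$purity_shape[[1]],
                              config$purity_shape[[2]])
  names(base_purity) <- patients
  pur <- base_purity[clinical$patient_id]
  on_trt <- clinical$time != "T1"
  pur[on_trt] <- pmin(pmax(pur[on_trt] - config$purity_drop +
                             stats::rnorm(sum(on_trt), 0, 0.05), 0.05), 0.99)
  clinical$purity <- round(unname(pur), 4)

  eff <- config_gene_effects(config)
  # features are modeled univariately, so each gene draws its own patient
  # random intercepts (genes x patients)
  b_pat <- matrix(stats::rnorm(config$n_genes * n, 0,
                               config$random_intercept_sd),
                  nrow = config$n_genes,
                  dimnames = list(eff$gene_id, patients))

  ns <- nrow(clinical)
  X_t2 <- as.numeric(clinical$time == "T2")
  X_t3 <- as.numeric(clinical$time == "T3")
  sub_names <- setdiff(SUBTYPES, SUBTYPES[1])
  X_sub <- sapply(sub_names, function(s) as.numeric(clinical$subtype == s))
  # per-sample linear predictor pieces shared by all genes in a block
  log2expr <- matrix(config$baseline_log2, nrow = config$n_genes, ncol = ns,
                     dimnames = list(eff$gene_id, clinical$sample_id))
  fixed <- outer(eff$beta_purity, clinical$purity) +
    outer(eff$beta_T2, X_t2) + outer(eff$beta_T3, X_t3)
  for (s in sub_names)
    fixed <- fixed + outer(eff[[paste0("beta_", s)]], as.numeric(X_sub[, s]))
  log2expr <- log2expr + fixed + b_pat[, clinical$patient_id] +
    matrix(stats::rnorm(config$n_genes * ns, 0, config$residual_sd),
           nrow = config$n_genes)
  expr <- 2^log2expr

  validate_clinical(clinical)
  validate_expression(expr)
  list(expression = expr, clinical = clinical,
       truth = list(gene_effects = eff, patient_intercepts = b_pat,
                    config = config))
}

#' Simulate bulk mixtures from a cell-type signature matrix
#'
#' Each mixture column is `signature %*% f` with fractions `f` drawn from a
#' flat Dirichlet over the cell types, plus Gaussian noise truncated at zero.
#'
#' @param signature genes x cell-types non-negative matrix (>= 2 types).
#' @param n_samples number of mixtures.
#' @param noise_sd Gaussian noise SD on the mixture scale (>= 0).
#' @param seed integer seed.
#' @param fractions optional samples x types matrix of fractions to use
#'   instead of Dirichlet draws (rows must sum to 1).
#' @return list `mixture` (genes x samples matrix) and `fractions`
#'   (samples x types matrix summing to 1 by row).
#' @export
simulate_mixtures <- function(signature, n_samples, noise_sd = 0, seed = 1L,
                              fractions = NULL) {
  if (ncol(signature) < 2) stop("signature needs >= 2 cell types")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  k <- ncol(signature)
  if (is.null(fractions)) {
    g <- matrix(stats::rgamma(n_samples * k, shape = 1), nrow = n_samples)
    fractions <- g / rowSums(g)
  } else {
    fractions <- as.matrix(fractions)
    if (ncol(fractions) != k || nrow(fractions) != n_samples)
      stop("fractions must be n_samples x n_types")
    if (any(abs(rowSums(fractions) - 1) > 1e-8))
      stop("fraction rows must sum to 1")
  }
  colnames(fractions) <- colnames(signature)
  mix <- signature %*% t(fractions)
  if (noise_sd > 0)
    mix <- pmax(mix + matrix(stats::rnorm(length(mix), 0, noise_sd),
                             nrow = nrow(mix)), 0)
  colnames(mix) <- sprintf("MIX%03d", seq_len(n_samples))
  rownames(fractions) <- colnames(mix)
  list(mixture = mix, fractions = fractions)
}

#' Default synthetic immune-cell signature matrix
#'
#' A synthetic 13-cell-type signature with block-structured marker genes,
#' standing in for proprietary leukocyte reference profiles. Each cell type
#' has `markers_per_type` high-expression marker genes on a low shared
#' background.
#'
#' @param n_types number of cell types (default 13).
#' @param markers_per_type markers per type.
#' @param marker_level,background_level expression levels (TPM-like).
#' @param seed integer seed for mild lognormal variation.
#' @return genes x types matrix.
#' @export
synthetic_signature_matrix <- function(n_types = 13, markers_per_type = 20,
                                       marker_level = 500,
                                       background_level = 10, seed = 99L) {
  set.seed(as.integer(seed))
  types <- c("T.CD8", "T.CD4.naive", "T.CD4.memory", "T.reg", "B.naive",
             "B.memory", "NK", "Mono", "M0", "M1", "M2", "Mast", "DC")
  types <- types[seq_len(n_types)]
  ng <- n_types * markers_per_type
  sig <- matrix(background_level *
                  stats::rlnorm(ng * n_types, 0, 0.1), nrow = ng)
  for (j in seq_len(n_types)) {
    rows <- ((j - 1) * markers_per_type + 1):(j * markers_per_type)
    sig[rows, j] <- marker_level * stats::rlnorm(markers_per_type, 0, 0.2)
  }
  dimnames(sig) <- list(sprintf("MK%03d", seq_len(ng)), types)
  sig
}

#' Simulate a histology-like image with planted nuclei
#'
#' Renders lymphocytes as small round dark nuclei (pixel area in [60, 150])
#' and non-lymphocytes as larger, irregular, less dark blobs (area > 200) on
#' a lighter textured tissue background. Grayscale intensities in [0, 1];
#' dark = stained nuclei. The ground truth records every planted cell.
#'
#' @param width,height image size in pixels.
#' @param n_lymphocytes,n_other planted cell counts.
#' @param seed integer seed.
#' @return list `image` (height x width matrix in [0,1]) and `truth`
#'   (data.frame x, y, type, area).
#' @export
simulate_histology_image <- function(width, height, n_lymphocytes, n_other,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  n_cells <- n_lymphocytes + n_other
  # generous packing bound: each cell needs a clear 40px-diameter site
  if (n_cells > 0 && (width * height) / 1600 < n_cells * 2)
    stop("image too small for requested cell counts")
  img <- matrix(0.85, nrow = height, ncol = width)
  # light tissue texture
  img <- img + matrix(stats::rnorm(width * height, 0, 0.02),
                      nrow = height, ncol = width)

  margin <- 20
  # Poisson-disk-ish placement by rejection
  centers <- matrix(NA_real_, nrow = n_cells, ncol = 2)
  placed <- 0L
  tries <- 0L
  min_dist <- 34
  while (placed < n_cells && tries < 200000L) {
    tries <- tries + 1L
    cx <- stats::runif(1, margin, width - margin)
    cy <- stats::runif(1, margin, height - margin)
    if (placed == 0L ||
        min((centers[seq_len(placed), 1] - cx)^2 +
            (centers[seq_len(placed), 2] - cy)^2) > min_dist^2) {
      placed <- placed + 1L
      centers[placed, ] <- c(cx, cy)
    }
  }
  if (placed < n_cells) stop("could not place cells without overlap")

  truth <- data.frame(x = numeric(0), y = numeric(0),
                      type = character(0), area = numeric(0),
                      stringsAsFactors = FALSE)
  yg <- matrix(seq_len(height), nrow = height, ncol = width)
  xg <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  draw_blob <- function(img, cx, cy, target_area, darkness, irregular) {
    r0 <- sqrt(target_area / pi)
    # local window
    w <- ceiling(r0 * 2.5) + 3
    xr <- max(1, round(cx - w)):min(width, round(cx + w))
    yr <- max(1, round(cy - w)):min(height, round(cy + w))
    dx <- outer(rep(1, length(yr)), xr - cx)
    dy <- outer(yr - cy, rep(1, length(xr)))
    if (irregular) {
      ang <- atan2(dy, dx)
      r_ang <- r0 * (1 + 0.35 * sin(3 * ang + stats::runif(1, 0, 2 * pi)) +
                       0.2 * cos(5 * ang + stats::runif(1, 0, 2 * pi)))
    } else {
      r_ang <- r0
    }
    mask <- sqrt(dx^2 + dy^2) <= r_ang
    sub <- img[yr, xr]
    sub[mask] <- pmin(sub[mask], darkness +
                        stats::rnorm(sum(mask), 0, 0.01))
    img[yr, xr] <- sub
    list(img = img, area = sum(mask))
  }

  idx <- 1L
  for (i in seq_len(n_lymphocytes)) {
    area_t <- stats::runif(1, 70, 140)
    res <- draw_blob(img, centers[idx, 1], centers[idx, 2], area_t,
                     darkness = 0.12, irregular = FALSE)
    img <- res$img
    truth <- rbind(truth, data.frame(x = centers[idx, 1], y = centers[idx, 2],
                                     type = "lymphocyte", area = res$area,
                                     stringsAsFactors = FALSE))
    idx <- idx + 1L
  }
  for (i in seq_len(n_other)) {
    area_t <- stats::runif(1, 300, 650)
    res <- draw_blob(img, centers[idx, 1], centers[idx, 2], area_t,
                     darkness = 0.45, irregular = TRUE)
    img <- res$img
    truth <- rbind(truth, data.frame(x = centers[idx, 1], y = centers[idx, 2],
                                     type = "other", area = res$area,
                                     stringsAsFactors = FALSE))
    idx <- idx + 1L
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, truth = truth)
}

#' Write a grayscale image matrix as PNG
#' @param image matrix in [0,1].
#' @param path output PNG path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read a PNG as a grayscale matrix
#' @param path PNG path.
#' @return matrix in [0,1] (RGB averaged if needed).
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
  a
}
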