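# Digital H&E-style lymphocyte quantification: Otsu segmentation with size
# filters and watershed splitting, a fixed 36-dimensional feature vector per
# nucleus candidate, a radial-kernel SVM classifier with probability output,
# the published score/size filters, tile-wise processing with global
# coordinate reconstruction, and TIL density per tissue area.

#' Segment nucleus candidates from a grayscale image
#'
#' Global Otsu threshold on inverted intensity (nuclei are dark), connected
#' components, then size filters: components smaller than `min_shape` are
#' discarded, larger than `failure_region` discarded as segmentation
#' failures, and components in `(max_shape, failure_region]` are split by
#' watershed on the distance transform with the pieces re-filtered.
#'
#' @param image matrix in [0, 1], dark nuclei on lighter tissue.
#' @param min_shape,max_shape,failure_region pixel-area filters
#'   (defaults 50 / 800 / 2000).
#' @return object of class `cell_candidates`: `table` (data.frame `id`,
#'   `x`, `y`, `area`) and `labels` (integer matrix, 0 = background).
#' @export
segment_nuclei <- function(image, min_shape = 50, max_shape = 800,
                           failure_region = 2000) {
  empty <- function() structure(
    list(table = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                            area = numeric(0)),
         labels = matrix(0L, nrow(image), ncol(image))),
    class = "cell_candidates")
  if (stats::sd(image) < 1e-8) return(empty())
  inv <- 1 - image
  thr <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1))
  mask <- inv > thr
  if (!any(mask) || all(mask)) return(empty())
  # blank tissue: Otsu splits plain texture noise; require real contrast
  if (mean(inv[mask]) - mean(inv[!mask]) < 0.1) return(empty())
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  keep_ok <- which(areas >= min_shape & areas <= max_shape)
  oversize <- which(areas > max_shape & areas <= failure_region)
  out <- matrix(0L, nrow(image), ncol(image))
  next_id <- 0L
  for (id in keep_ok) {
    next_id <- next_id + 1L
    out[lab == id] <- next_id
  }
  if (length(oversize)) {
    big_mask <- matrix(lab %in% oversize, nrow(image), ncol(image))
    dm <- EBImage::distmap(EBImage::Image(big_mask))
    ws <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
    piece_areas <- tabulate(ws[ws > 0])
    for (pid in which(piece_areas >= min_shape &
                        piece_areas <= failure_region)) {
      next_id <- next_id + 1L
      out[ws == pid] <- next_id
    }
  }
  if (next_id == 0L) return(empty())
  idx <- which(out > 0)
  ids <- out[idx]
  rr <- (idx - 1) %% nrow(out) + 1
  cc <- (idx - 1) %/% nrow(out) + 1
  tab <- data.frame(id = seq_len(next_id),
                    x = as.numeric(tapply(cc, ids, mean)),
                    y = as.numeric(tapply(rr, ids, mean)),
                    area = as.numeric(tabulate(ids, next_id)))
  structure(list(table = tab, labels = out), class = "cell_candidates")
}

#' @export
print.cell_candidates <- function(x, ...) {
  cat("Segmented", nrow(x$table), "nucleus candidate(s)\n")
  invisible(x)
}

#' Names of the 36 per-candidate features
#' @return character vector of length 36.
#' @export
til_feature_names <- function() {
  c("area", "perimeter", "radius.mean", "radius.sd", "radius.min",
    "radius.max", "major.axis", "minor.axis", "eccentricity", "circularity",
    "int.mean", "int.sd", "int.mad", "int.min", "int.max", "int.q10",
    "int.q25", "int.q50", "int.q75", "int.q90", "int.total", "int.cv",
    "int.skew", "int.kurtosis",
    "border.mean", "center.border.contrast", "grad.mean", "grad.sd",
    "bg.mean", "fg.bg.contrast", "hist.entropy", "hist.energy",
    "smoothness", "int.range", "int.iqr", "aspect.ratio")
}

#' Extract the fixed 36-feature vector per candidate
#'
#' Ten shape features (pixel geometry only), fourteen intensity features on
#' the inverted grayscale within the mask, and twelve texture/context
#' features (border contrast, gradients, local background, histogram
#' statistics). Shape features depend only on the segmentation mask, so
#' rescaling image brightness leaves them unchanged; `area` equals the
#' component pixel count exactly.
#'
#' @param candidates `cell_candidates` from [segment_nuclei()].
#' @param image the image the candidates came from.
#' @return n x 36 numeric matrix with [til_feature_names()] columns.
#' @export
extract_features <- function(candidates, image) {
  tab <- candidates$table
  labs <- candidates$labels
  if (!identical(dim(labs), dim(image)))
    stop("candidates do not match image dimensions")
  inv <- 1 - image
  n <- nrow(tab)
  feats <- matrix(NA_real_, n, 36,
                  dimnames = list(NULL, til_feature_names()))
  nr <- nrow(image); nc <- ncol(image)
  for (i in seq_len(n)) {
    idx <- which(labs == tab$id[[i]])
    rr <- (idx - 1) %% nr + 1
    cc <- (idx - 1) %/% nr + 1
    if (any(rr < 1 | rr > nr | cc < 1 | cc > nc))
      stop("candidate outside image bounds")
    v <- inv[idx]
    area <- length(idx)
    cy <- mean(rr); cx <- mean(cc)
    d <- sqrt((rr - cy)^2 + (cc - cx)^2)
    # boundary: pixels with a 4-neighbour outside the component
    inside <- matrix(FALSE, nr, nc); inside[idx] <- TRUE
    up <- rr > 1 & !inside[cbind(pmax(rr - 1, 1), cc)]
    dn <- rr < nr & !inside[cbind(pmin(rr + 1, nr), cc)]
    lf <- cc > 1 & !inside[cbind(rr, pmax(cc - 1, 1))]
    rt <- cc < nc & !inside[cbind(rr, pmin(cc + 1, nc))]
    edge <- rr == 1 | rr == nr | cc == 1 | cc == nc
    on_border <- up | dn | lf | rt | edge
    perim <- sum(on_border)
    # second moments -> axes
    mrr <- mean((rr - cy)^2); mcc <- mean((cc - cx)^2)
    mrc <- mean((rr - cy) * (cc - cx))
    tr2 <- (mrr + mcc) / 2
    det_ <- sqrt(max(((mrr - mcc) / 2)^2 + mrc^2, 0))
    l1 <- tr2 + det_; l2 <- max(tr2 - det_, 1e-9)
    ecc <- sqrt(max(1 - l2 / l1, 0))
    qs <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
    mu <- mean(v); sdv <- stats::sd(v)
    if (!is.finite(sdv)) sdv <- 0
    skew <- if (sdv > 0) mean(((v - mu) / sdv)^3) else 0
    kurt <- if (sdv > 0) mean(((v - mu) / sdv)^4) - 3 else 0
    # gradients within the bounding box, masked
    gmag <- {
      r1 <- max(min(rr) - 1, 1); r2 <- min(max(rr) + 1, nr)
      c1 <- max(min(cc) - 1, 1); c2 <- min(max(cc) + 1, nc)
      box <- inv[r1:r2, c1:c2, drop = FALSE]
      gx <- box[, -1, drop = FALSE] - box[, -ncol(box), drop = FALSE]
      gy <- box[-1, , drop = FALSE] - box[-nrow(box), , drop = FALSE]
      gm <- sqrt(gx[-nrow(gx), , drop = FALSE]^2 + gy[, -ncol(gy), drop = FALSE]^2)
      msk <- inside[r1:r2, c1:c2][seq_len(nrow(gm)), seq_len(ncol(gm))]
      gm[msk]
    }
    bg <- {
      r1 <- max(min(rr) - 3, 1); r2 <- min(max(rr) + 3, nr)
      c1 <- max(min(cc) - 3, 1); c2 <- min(max(cc) + 3, nc)
      box <- inv[r1:r2, c1:c2, drop = FALSE]
      msk <- inside[r1:r2, c1:c2]
      if (any(!msk)) mean(box[!msk]) else 0
    }
    h <- tabulate(pmin(floor(v * 8) + 1, 8), 8) / area
    hpos <- h[h > 0]
    feats[i, ] <- c(
      area, perim, mean(d), if (length(d) > 1) stats::sd(d) else 0,
      min(d), max(d),
      2 * sqrt(l1), 2 * sqrt(l2), ecc,
      4 * pi * area / max(perim^2, 1),
      mu, sdv, stats::mad(v, constant = 1), min(v), max(v),
      qs[1], qs[2], qs[3], qs[4], qs[5], sum(v),
      if (mu > 0) sdv / mu else 0, skew, kurt,
      mean(v[on_border]), mu - mean(v[on_border]),
      if (length(gmag)) mean(gmag) else 0,
      if (length(gmag) > 1) stats::sd(gmag) else 0,
      bg, mu - bg, -sum(hpos * log2(hpos)), sum(h^2),
      1 - 1 / (1 + sdv^2), max(v) - min(v), qs[4] - qs[2],
      sqrt(l1) / sqrt(l2))
  }
  feats[!is.finite(feats)] <- 0
  feats
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Train the lymphocyte SVM classifier
#'
#' C-classification SVM with a radial kernel and probability output on the
#' 36-feature matrix.
#'
#' @param features n x 36 matrix.
#' @param labels factor or character with levels "lymphocyte" / "other";
#'   both classes must be present (>= 10 each recommended).
#' @param seed integer seed (probability model fitting resamples).
#' @return fitted `e1071::svm` object.
#' @export
train_classifier <- function(features, labels, seed = 1L) {
  labels <- factor(labels, levels = c("lymphocyte", "other"))
  if (length(unique(stats::na.omit(labels))) < 2)
    stop("both classes must be present")
  if (any(table(labels) < 10))
    warning("fewer than 10 examples in a class; classifier may be unstable")
  set.seed(as.integer(seed))
  e1071::svm(x = features, y = labels, type = "C-classification",
             kernel = "radial", probability = TRUE)
}

#' Lymphocyte class probabilities for candidates
#' @param classifier from [train_classifier()].
#' @param features n x 36 matrix.
#' @return numeric vector of lymphocyte probabilities in [0, 1].
#' @export
classify_candidates <- function(classifier, features) {
  if (!nrow(features)) return(numeric(0))
  pred <- stats::predict(classifier, features, probability = TRUE)
  attr(pred, "probabilities")[, "lymphocyte"]
}

#' Apply the published score and size filters
#'
#' A candidate is a lymphocyte when its lymphocyte probability is at least
#' `prob_min` (0.97) and its area lies in `[size_min, size_max]` = [60, 150];
#' a non-lymphocyte when its probability is at most `prob_nonlymph` (0.1);
#' a large cell when it is not classed lymphocyte and its area is at least
#' the third quartile of areas among cells larger than 200 px.
#'
#' @param candidates data.frame with at least `area` and `prob` columns.
#' @param prob_min,prob_nonlymph,size_min,size_max filter parameters.
#' @return list `lymphocytes`, `non_lymphocytes`, `large_cells`
#'   (data.frames).
#' @export
filter_lymphocytes <- function(candidates, prob_min = 0.97,
                               prob_nonlymph = 0.1,
                               size_min = 60, size_max = 150) {
  stopifnot(all(c("area", "prob") %in% names(candidates)))
  is_lymph <- candidates$prob >= prob_min &
    candidates$area >= size_min & candidates$area <= size_max
  is_non <- candidates$prob <= prob_nonlymph
  big <- candidates$area[candidates$area > 200]
  q3 <- if (length(big)) stats::quantile(big, 0.75, names = FALSE) else Inf
  labeled_lymph <- candidates$prob >= 0.5
  is_large <- !labeled_lymph & candidates$area >= q3
  list(lymphocytes = candidates[is_lymph, , drop = FALSE],
       non_lymphocytes = candidates[is_non, , drop = FALSE],
       large_cells = candidates[is_large, , drop = FALSE])
}

#' Tile-wise segmentation and classification with global coordinates
#'
#' Processes the image in `tile_size` x `tile_size` tiles (with a small
#' overlap so border nuclei are seen whole), reconstructs global centroid
#' coordinates from the tile offsets, and resolves border duplicates by
#' centroid ownership: a cell belongs to the tile containing its centroid.
#'
#' @param image grayscale matrix.
#' @param classifier from [train_classifier()]; NULL skips classification.
#' @param tile_size tile edge in pixels, default 2050.
#' @param overlap overlap margin in pixels, default 40.
#' @param ... passed to [segment_nuclei()].
#' @return data.frame `x`, `y` (global), `area`, `prob` (NA without a
#'   classifier).
#' @export
tile_process <- function(image, classifier = NULL, tile_size = 2050,
                         overlap = 40, ...) {
  nr <- nrow(image); nc <- ncol(image)
  tiles_y <- seq(1, nr, by = tile_size)
  tiles_x <- seq(1, nc, by = tile_size)
  out <- list()
  for (ty in tiles_y) for (tx in tiles_x) {
    y2 <- min(ty + tile_size - 1, nr); x2 <- min(tx + tile_size - 1, nc)
    ry <- max(ty - overlap, 1):min(y2 + overlap, nr)
    rx <- max(tx - overlap, 1):min(x2 + overlap, nc)
    sub <- image[ry, rx, drop = FALSE]
    cand <- segment_nuclei(sub, ...)
    if (!nrow(cand$table)) next
    gx <- cand$table$x + rx[1] - 1
    gy <- cand$table$y + ry[1] - 1
    own <- gx >= tx & gx <= x2 & gy >= ty & gy <= y2
    if (!any(own)) next
    prob <- if (is.null(classifier)) rep(NA_real_, nrow(cand$table))
            else classify_candidates(classifier, extract_features(cand, sub))
    out[[length(out) + 1L]] <-
      data.frame(x = gx[own], y = gy[own], area = cand$table$area[own],
                 prob = prob[own])
  }
  if (!length(out))
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      prob = numeric(0)))
  do.call(rbind, out)
}

#' TIL density from a lymphocyte count and tissue area
#'
#' Tissue area is the count of pixels darker than `white_cutoff` (glass /
#' empty background is near-white), converted to mm^2 by the pixel scale.
#'
#' @param lymphocyte_count non-negative count.
#' @param image grayscale matrix.
#' @param um_per_px microns per pixel, default 0.5 (20x convention).
#' @param white_cutoff intensity above which a pixel is background glass.
#' @param large_cell_count optional count carried through.
#' @return object of class `til_quant`: `lymphocyte_count`,
#'   `tissue_area_px`, `tissue_area_mm2`, `density` (cells/mm^2),
#'   `large_cell_count`.
#' @export
compute_density <- function(lymphocyte_count, image, um_per_px = 0.5,
                            white_cutoff = 0.98, large_cell_count = NA) {
  px <- sum(image < white_cutoff)
  if (px == 0) stop("zero tissue area")
  mm2 <- px * (um_per_px / 1000)^2
  structure(list(lymphocyte_count = lymphocyte_count,
                 tissue_area_px = px, tissue_area_mm2 = mm2,
                 density = lymphocyte_count / mm2,
                 large_cell_count = large_cell_count),
            class = "til_quant")
}

#' @export
print.til_quant <- function(x, ...) {
  cat("TIL quantification:", x$lymphocyte_count, "lymphocytes over",
      signif(x$tissue_area_mm2, 4), "mm^2 =>",
      signif(x$density, 4), "cells/mm^2\n")
  invisible(x)
}

#' Train a classifier on synthetic nuclei
#'
#' Generates training images with planted lymphocytes and larger
#' non-lymphocyte cells, segments them, labels candidates by nearest planted
#' cell, and trains the SVM. Emulates supervised training on
#' pathologist-marked cells when no marked set is available.
#'
#' @param n_images training images, default 4.
#' @param seed integer seed.
#' @return fitted classifier.
#' @export
train_til_classifier <- function(n_images = 4, seed = 101L) {
  feats <- list(); labs <- character(0)
  for (i in seq_len(n_images)) {
    sim <- simulate_histology_image(900, 900, 70, 48,
                                    seed = as.integer(seed) + i)
    cand <- segment_nuclei(sim$image)
    if (!nrow(cand$table)) next
    f <- extract_features(cand, sim$image)
    lab <- vapply(seq_len(nrow(cand$table)), function(j) {
      d2 <- (sim$truth$x - cand$table$x[[j]])^2 +
        (sim$truth$y - cand$table$y[[j]])^2
      ix <- which.min(d2)
      if (d2[[ix]] < 15^2)
        if (sim$truth$type[[ix]] == "lymphocyte") "lymphocyte" else "other"
      else NA_character_
    }, character(1))
    keep <- !is.na(lab)
    feats[[length(feats) + 1L]] <- f[keep, , drop = FALSE]
    labs <- c(labs, lab[keep])
  }
  train_classifier(do.call(rbind, feats), labs, seed = seed)
}

#' End-to-end TIL quantification of one image
#'
#' Tiles, segments, classifies, applies the published filters, and computes
#' density.
#'
#' @param image grayscale matrix.
#' @param classifier from [train_classifier()] / [train_til_classifier()].
#' @param tile_size,um_per_px see [tile_process()] and [compute_density()].
#' @param ... passed to [filter_lymphocytes()].
#' @return `til_quant` object with the filtered cell table attached as
#'   attribute `cells`.
#' @export
quantify_tils <- function(image, classifier, tile_size = 2050,
                          um_per_px = 0.5, ...) {
  cells <- tile_process(image, classifier, tile_size = tile_size)
  filt <- filter_lymphocytes(cells, ...)
  q <- compute_density(nrow(filt$lymphocytes), image, um_per_px = um_per_px,
                       large_cell_count = nrow(filt$large_cells))
  attr(q, "cells") <- cells
  q
}
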