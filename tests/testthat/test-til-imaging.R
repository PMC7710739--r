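test_that("segmentation finds planted nuclei and applies size filters", {
  blank <- simulate_histology_image(400, 400, 0, 0, seed = 1)
  expect_equal(nrow(segment_nuclei(blank$image)$table), 0)

  # a single planted disk of area ~100
  img <- matrix(0.9, 200, 200)
  yy <- matrix(1:200, 200, 200); xx <- t(yy)
  disk <- (yy - 100)^2 + (xx - 100)^2 <= 5.64^2   # area ~ pi*5.64^2 ~ 100
  img[disk] <- 0.1
  cand <- segment_nuclei(img)
  expect_equal(nrow(cand$table), 1)
  expect_lt(abs(cand$table$area - 100) / 100, 0.15)

  # an oversized blob beyond the failure region yields nothing
  img2 <- matrix(0.9, 200, 200)
  blob <- (yy - 100)^2 + (xx - 100)^2 <= 29^2    # area ~ 2642 > 2000
  img2[blob] <- 0.1
  expect_equal(nrow(segment_nuclei(img2)$table), 0)

  # uniform image: no candidates
  expect_equal(nrow(segment_nuclei(matrix(0.5, 100, 100))$table), 0)
})

test_that("features are deterministic, 36-dimensional, and separable", {
  sim <- simulate_histology_image(500, 500, 12, 6, seed = 4)
  cand <- segment_nuclei(sim$image)
  f1 <- extract_features(cand, sim$image)
  f2 <- extract_features(cand, sim$image)
  expect_identical(f1, f2)
  expect_equal(ncol(f1), 36)
  expect_identical(colnames(f1), til_feature_names())
  # area feature equals the component pixel count exactly
  expect_equal(unname(f1[, "area"]), cand$table$area)

  # brightness change touches intensity features only, never shape
  dim_img <- 1 - (1 - sim$image) * 0.5
  f3 <- extract_features(cand, dim_img)
  shape_cols <- c("area", "perimeter", "radius.mean", "radius.sd",
                  "radius.min", "radius.max", "major.axis", "minor.axis",
                  "eccentricity", "circularity", "aspect.ratio")
  expect_equal(f1[, shape_cols], f3[, shape_cols])
  expect_false(isTRUE(all.equal(f1[, "int.mean"], f3[, "int.mean"])))
})

test_that("the classifier separates planted classes and calibrates on noise", {
  sim <- simulate_histology_image(800, 800, 50, 35, seed = 5)
  cand <- segment_nuclei(sim$image)
  f <- extract_features(cand, sim$image)
  lab <- vapply(seq_len(nrow(cand$table)), function(j) {
    d2 <- (sim$truth$x - cand$table$x[[j]])^2 +
      (sim$truth$y - cand$table$y[[j]])^2
    if (sim$truth$type[[which.min(d2)]] == "lymphocyte") "lymphocyte" else "other"
  }, character(1))
  clf <- train_classifier(f, lab, seed = 1)
  pr <- classify_candidates(clf, f)
  expect_true(all(pr >= 0 & pr <= 1))
  pred <- ifelse(pr >= 0.5, "lymphocyte", "other")
  expect_gt(mean(pred == lab), 0.97)

  # shuffled labels: cross-validated accuracy collapses to chance
  set.seed(2)
  shuf <- sample(lab)
  folds <- sample(rep(1:4, length.out = length(shuf)))
  accs <- vapply(1:4, function(k) {
    tr <- folds != k
    if (length(unique(shuf[tr])) < 2) return(NA_real_)
    cl <- train_classifier(f[tr, ], shuf[tr], seed = k)
    mean(ifelse(classify_candidates(cl, f[!tr, , drop = FALSE]) >= 0.5,
                "lymphocyte", "other") == shuf[!tr])
  }, numeric(1))
  expect_lt(abs(mean(accs, na.rm = TRUE) - 0.5), 0.15)
  expect_error(train_classifier(f, rep("lymphocyte", nrow(f))), "both classes")
})

test_that("published score and size filters are enforced exactly", {
  cand <- data.frame(
    area = c(100, 160, 100, 100, 50, 300, 400, 250, 500),
    prob = c(0.98, 0.98, 0.5, 0.05, 0.99, 0.02, 0.03, 0.04, 0.01))
  filt <- filter_lymphocytes(cand)
  # prob .98 area 100 in; area 160 fails the size gate; prob .5 dead zone
  expect_equal(nrow(filt$lymphocytes), 1)
  expect_equal(filt$lymphocytes$area, 100)
  expect_true(all(filt$non_lymphocytes$prob <= 0.1))
  expect_false(any(filt$lymphocytes$prob == 0.5))
  # large cells: area >= Q3 of areas among cells > 200
  q3 <- quantile(c(300, 400, 250, 500), 0.75, names = FALSE)
  expect_setequal(filt$large_cells$area,
                  cand$area[cand$prob < 0.5 & cand$area >= q3])
  # raising the probability cutoff never increases the count
  counts <- vapply(c(0.5, 0.8, 0.97, 0.99),
                   function(p) nrow(filter_lymphocytes(cand, prob_min = p)$lymphocytes),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tiling reconstructs global coordinates and preserves counts", {
  sim <- simulate_histology_image(900, 900, 60, 20, seed = 6)
  untiled <- segment_nuclei(sim$image)
  tiled <- tile_process(sim$image, classifier = NULL, tile_size = 2050)
  # image smaller than one tile: identical to untiled processing
  expect_equal(nrow(tiled), nrow(untiled$table))
  expect_equal(sort(tiled$area), sort(untiled$table$area))

  # across tiles: counts survive and coordinates are global
  tiled4 <- tile_process(sim$image, classifier = NULL, tile_size = 450)
  expect_lt(abs(nrow(tiled4) - nrow(untiled$table)), 5)
  expect_true(all(tiled4$x >= 1 & tiled4$x <= 900))
  nn <- vapply(seq_len(nrow(tiled4)), function(i)
    min((sim$truth$x - tiled4$x[[i]])^2 + (sim$truth$y - tiled4$y[[i]])^2),
    numeric(1))
  expect_lt(sqrt(max(nn)), 6)   # every detection near a planted cell

  # offset arithmetic: a cell in tile (1,1) at local (10,10) maps to
  # global (tile+10, tile+10)
  ts <- 450
  img <- matrix(0.9, 900, 900)
  yy <- matrix(1:900, 900, 900); xx <- t(yy)
  disk <- (yy - (ts + 10))^2 + (xx - (ts + 10))^2 <= 5.6^2
  img[disk] <- 0.1
  got <- tile_process(img, classifier = NULL, tile_size = ts)
  expect_equal(nrow(got), 1)
  expect_equal(got$x, ts + 10, tolerance = 1)
  expect_equal(got$y, ts + 10, tolerance = 1)
})

test_that("density bookkeeping follows the unit laws", {
  img <- matrix(0.5, 100, 100)   # all tissue
  q <- compute_density(0, img)
  expect_equal(q$density, 0)
  # 50 cells over exactly 1 mm^2: 2000x2000 px at 0.5 um/px
  q2 <- compute_density(50, matrix(0.5, 2000, 2000), um_per_px = 0.5)
  expect_equal(q2$tissue_area_mm2, 1)
  expect_equal(q2$density, 50)
  # halving um/px quarters the area and quadruples density
  q3 <- compute_density(50, matrix(0.5, 2000, 2000), um_per_px = 0.25)
  expect_equal(q3$tissue_area_mm2, 0.25)
  expect_equal(q3$density, 200)
  expect_error(compute_density(1, matrix(1, 10, 10)), "zero tissue")
})
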