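# Feature registry, lumen shape descriptors and global/local aggregation.

test_that("the registry has 67 features: 29 global, 38 local, 17 categories", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 67L)
  expect_equal(sum(reg$scope == "global"), 29L)
  expect_equal(sum(reg$scope == "local"), 38L)
  expect_setequal(unique(reg$category), 1:17)
  expect_true(all(table(reg$category) >= 1))
  expect_silent(validate_registry(reg))
})

test_that("registries round-trip through JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  write_registry(feature_registry(), p)
  reg2 <- read_registry(p)
  expect_equal(reg2$feature_id, feature_registry()$feature_id)
})

test_that("disc shape descriptors approach their continuous limits", {
  for (R in c(15, 30, 60)) {
    l <- lumen_object(disc_pixels(R))
    expect_lte(lumen_distortion(l), 0.05)
    expect_lt(abs(lumen_convex_ratio(l) - 1), 0.03)
    expect_lte(lumen_mbc_ratio(l), 1.1)
    expect_gte(lumen_mbc_ratio(l), 1)
    expect_lt(abs(lumen_roundness(l) - 4 * pi / R) / (4 * pi / R), 0.1)
    sym <- lumen_symmetry_indices(l)
    expect_lt(sym[["boundary_sym"]], 0.05)
    expect_lt(sym[["area_sym"]], 0.05)
  }
})

test_that("square and bar match their enclosing-circle closed forms", {
  sq <- lumen_object(square_pixels(50))
  expect_lt(abs(lumen_mbc_ratio(sq) - pi / 2) / (pi / 2), 0.05)
  expect_lt(abs(lumen_convex_ratio(sq) - 1), 0.03)
  # same-area square is less round than the disc (roundness grows)
  dk <- lumen_object(disc_pixels(28))  # area ~ 2463 ~ 50^2
  expect_gt(lumen_roundness(sq), lumen_roundness(dk))
  bar <- lumen_object(cbind(0L, 0:39))
  expect_lt(abs(lumen_mbc_ratio(bar) - pi * 40 / 4) / (pi * 40 / 4), 0.1)
})

test_that("ellipse distortion matches an arclength-weighted oracle", {
  a <- 40; b <- 20
  l <- lumen_object(ellipse_pixels(a, b))
  th <- seq(0, 2 * pi, length.out = 20001)[-1]
  ex <- a * cos(th); ey <- b * sin(th)
  seg <- sqrt(diff(c(ex, ex[1]))^2 + diff(c(ey, ey[1]))^2)
  w <- seg / sum(seg)
  r <- sqrt(ex^2 + ey^2)
  mu <- sum(w * r)
  cv <- sqrt(sum(w * (r - mu)^2)) / mu
  expect_lt(abs(lumen_distortion(l) - cv) / cv, 0.07)
})

test_that("asymmetric shapes score above symmetric ones", {
  Lpx <- rbind(as.matrix(expand.grid(0:29, 0:7)),
               as.matrix(expand.grid(22:29, 8:24)))
  l <- lumen_object(Lpx)
  sym <- lumen_symmetry_indices(l)
  expect_gt(sym[["area_sym"]], 0.1)
  # mirror image across a grid axis has identical indices
  lm <- lumen_object(cbind(Lpx[, 1], max(Lpx[, 2]) - Lpx[, 2]))
  expect_equal(lumen_symmetry_indices(lm), sym)
})

test_that("hull and enclosing-circle ratios order correctly on random blobs", {
  set.seed(8)
  for (i in 1:12) {
    n <- sample(40:200, 1)
    px <- unique(cbind(sample(0:25, n, TRUE), sample(0:25, n, TRUE)))
    # keep the largest 4-connected component to get a valid object
    pm <- histomorph:::px_to_mask(px)
    lab <- as.matrix(EBImage::bwlabel(pm$mask * 1L))
    big <- which.max(tabulate(lab[lab > 0]))
    idx <- which(lab == big, arr.ind = TRUE)
    px <- cbind(idx[, 1] - 1L + pm$off[1], idx[, 2] - 1L + pm$off[2])
    if (nrow(px) < 5) next
    l <- lumen_object(px)
    expect_gte(lumen_convex_ratio(l), 1)
    expect_gte(lumen_mbc_ratio(l), lumen_convex_ratio(l) - 1e-9)
  }
})

test_that("shape descriptors are invariant to translation and 90-degree rotation", {
  px <- ellipse_pixels(18, 9, theta = 0.4)
  feats <- function(p) {
    l <- lumen_object(p)
    c(lumen_roundness(l), lumen_distortion(l), lumen_mbc_ratio(l),
      lumen_convex_ratio(l))
  }
  f0 <- feats(px)
  expect_equal(feats(px + 17L), f0)                           # translation
  f90 <- feats(cbind(px[, 2], max(px[, 1]) - px[, 1]))        # rotation
  expect_true(all(abs(f90 - f0) / f0 < 0.02))
})

test_that("cytoplasm association reads the ring composition", {
  H <- 60; W <- 60
  lum <- circle_mask(H, W, c(30, 30), 10)
  l <- lumen_object(which(lum, arr.ind = TRUE) - 1L)
  epi <- binary_mask(ring_mask(H, W, c(30, 30), 10, 20))
  pink <- rgb_image(he_fill(he_canvas(H, W, HE_PINK), lum, HE_WHITE))
  expect_equal(lumen_cytoplasm_association(l, pink, epi), 1.0)
  blue <- rgb_image(he_fill(he_canvas(H, W, HE_BLUE), lum, HE_WHITE))
  expect_equal(lumen_cytoplasm_association(l, blue, epi), 0.0)
  # left half pink, right half blue: about one half
  half <- he_canvas(H, W, HE_PINK)
  half <- he_fill(half, col(matrix(0, H, W)) > 30, HE_BLUE)
  half <- he_fill(half, lum, HE_WHITE)
  v <- lumen_cytoplasm_association(l, rgb_image(half), epi)
  expect_lt(abs(v - 0.5), 0.05)
})

test_that("nucleus-lumen distances match a brute-force oracle", {
  H <- 80; W <- 80
  lum_mask <- circle_mask(H, W, c(40, 25), 10)
  lum <- lumen_object(which(lum_mask, arr.ind = TRUE) - 1L)
  nuc <- nucleus_object(which(circle_mask(H, W, c(40, 60), 4),
                              arr.ind = TRUE) - 1L)
  seg <- manual_seg(H, W, lumens = list(lum), nuclei = list(nuc))
  eq <- epithelium_quantities(seg)
  lp <- lum$pixels
  brute <- min(sqrt((lp[, 1] - nuc$centroid[1])^2 +
                      (lp[, 2] - nuc$centroid[2])^2))
  expect_lt(abs(eq$nucleus_lumen_dist[1] - brute), 1.5)
})

test_that("spatial entropy is maximal on a uniform grid, zero when clustered", {
  H <- 80; W <- 80
  g <- feat_config()$entropy_grid
  # one nucleus per grid cell, uniformly
  step <- 80 / g
  cents <- as.matrix(expand.grid(seq(step / 2, 80 - step / 2, by = step),
                                 seq(step / 2, 80 - step / 2, by = step)))
  nucs <- lapply(seq_len(nrow(cents)), function(i)
    nucleus_object(matrix(round(cents[i, ]), 1, 2)))
  seg <- manual_seg(H, W, nuclei = nucs)
  eq <- epithelium_quantities(seg)
  expect_equal(eq$spatial_entropy, 1.0, tolerance = 1e-6)
  # all nuclei in one tight cluster
  nucs2 <- lapply(1:9, function(i)
    nucleus_object(matrix(c(40 + i %% 3, 40 + i %/% 3), 1, 2)))
  eq2 <- epithelium_quantities(manual_seg(H, W, nuclei = nucs2))
  expect_equal(eq2$spatial_entropy, 0)
})

test_that("isolated and far counts follow the configured distances", {
  H <- 200; W <- 200
  mk <- function(r, c) nucleus_object(matrix(c(r, c), 1, 2))
  # two nuclei 20 px apart (neighbours), one 150 px away (isolated)
  nucs <- list(mk(20, 20), mk(20, 40), mk(170, 170))
  lum <- lumen_object(which(circle_mask(H, W, c(20, 30), 8),
                            arr.ind = TRUE) - 1L)
  seg <- manual_seg(H, W, lumens = list(lum), nuclei = nucs)
  eq <- epithelium_quantities(seg)
  expect_equal(sum(eq$isolated), 1L)
  expect_equal(sum(eq$far), 1L)   # only the distant one is far (> 80 px)
})

test_that("global aggregation does the arithmetic", {
  H <- 150; W <- 150
  mknuc <- function(n, r0, c0) {
    px <- which(circle_mask(H, W, c(r0, c0), 10), arr.ind = TRUE) - 1L
    nucleus_object(px[seq_len(n), , drop = FALSE])
  }
  nucs <- list(mknuc(10, 30, 30), mknuc(20, 30, 100), mknuc(30, 100, 60))
  seg <- manual_seg(H, W, nuclei = nucs)
  fv <- extract_features(seg, rgb_image(he_canvas(H, W, HE_PINK)))
  expect_equal(unname(fv$values["G_AVG_nucleus_area"]), 20)
  expect_equal(unname(fv$values["G_TOT_nucleus_area"]), 60)
  expect_equal(unname(fv$values["G_STD_nucleus_area"]), 10)
  expect_equal(unname(fv$values["G_TOT_nucleus_count"]), 3)
})

test_that("window counts partition the global count when windows tile", {
  smp <- render_sample(tissue_params("cancer", seed = 41, img_size = 200))
  seg <- segment_sample(smp$pair)
  cfg <- feat_config(window = 100, stride = 100, min_cover = 0)
  fv <- extract_features(seg, smp$pair$he, cfg = cfg)
  # stride = window size: 4 disjoint windows tile the 200x200 image
  eqn <- epithelium_quantities(seg, cfg)
  wins <- list(c(0, 0), c(0, 100), c(100, 0), c(100, 100))
  counts <- vapply(wins, function(w) {
    sum(eqn$centroids[, 1] >= w[1] & eqn$centroids[, 1] < w[1] + 100 &
          eqn$centroids[, 2] >= w[2] & eqn$centroids[, 2] < w[2] + 100)
  }, numeric(1))
  expect_equal(sum(counts), eqn$nucleus_count)
  expect_equal(unname(fv$values["L_MAX_nucleus_count"]), max(counts))
})

test_that("the missing policy zeroes lumen features and flags the vector", {
  seg <- manual_seg(60, 60, nuclei = list(
    nucleus_object(which(circle_mask(60, 60, c(30, 30), 4),
                         arr.ind = TRUE) - 1L)))
  fv <- extract_features(seg, rgb_image(he_canvas(60, 60, HE_PINK)))
  expect_true(fv$missing_policy_applied)
  expect_false(any(is.na(fv$values)))
  expect_equal(unname(fv$values["G_AVG_lumen_roundness"]), 0)
  expect_equal(unname(fv$values["G_TOT_lumen_count"]), 0)
})
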