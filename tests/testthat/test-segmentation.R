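# Lumen and nucleus detection on constructed fixtures.

# One gland: white disc lumen ringed by epithelium, inside a pink tissue
# disc on white glass.
gland_fixture <- function(H = 120, W = 120, lumen_R = 12, ring_w = 8,
                          ctr = c(60, 60), epi_ring = TRUE) {
  tissue <- circle_mask(H, W, ctr, 50)
  arr <- he_canvas(H, W, c(255, 255, 255))
  arr <- he_fill(arr, tissue, HE_PINK)
  lum <- circle_mask(H, W, ctr, lumen_R)
  arr <- he_fill(arr, lum, HE_WHITE)
  epi <- if (epi_ring) ring_mask(H, W, ctr, lumen_R, lumen_R + ring_w)
         else matrix(FALSE, H, W)
  list(he = rgb_image(arr), epi = binary_mask(epi),
       tissue = binary_mask(tissue & !lum), lumen_mask = lum)
}

test_that("epithelium maps through the identity transform", {
  ir <- matrix(1L, 10, 10)
  pair <- sample_pair(rgb_image(he_canvas(10, 10)), label_image(ir))
  reg <- structure(list(params = affine_params()),
                   class = "registration_result")
  epi <- epithelium_mask_from_ir(pair, reg)
  expect_true(all(epi$mask))

  ir2 <- matrix(2L, 10, 10)
  pair2 <- sample_pair(rgb_image(he_canvas(10, 10)), label_image(ir2))
  expect_false(any(epithelium_mask_from_ir(pair2, reg)$mask))
})

test_that("a white disc ringed by epithelium is one complete lumen", {
  fx <- gland_fixture()
  lum <- detect_complete_lumens(fx$he, fx$epi)
  expect_length(lum, 1L)
  expect_true(lum[[1]]$complete)
  expect_equal(lum[[1]]$area_px, sum(fx$lumen_mask))
  expect_lt(max(abs(lum[[1]]$centroid - c(60, 60))), 1)
})

test_that("a white disc without epithelial lining is rejected", {
  fx <- gland_fixture(epi_ring = FALSE)
  expect_length(detect_complete_lumens(fx$he, fx$epi), 0L)
})

test_that("the minimum-area filter drops tiny white spots", {
  fx <- gland_fixture()
  # add a 4-px white spot ringed by epithelium
  arr <- fx$he$pixels
  spot <- matrix(FALSE, 120, 120); spot[20:21, 20:21] <- TRUE
  arr <- he_fill(arr, spot, HE_WHITE)
  epi <- fx$epi$mask | ring_mask(120, 120, c(20, 20), 2, 8)
  lum <- detect_complete_lumens(rgb_image(arr), binary_mask(epi))
  expect_length(lum, 1L)   # only the big disc survives
})

test_that("edge lumens are found and crescent artifacts rejected", {
  H <- 140; W <- 140; ctr <- c(70, 70)
  tissue_full <- circle_mask(H, W, ctr, 60)
  # a half-moon notch cutting the tissue edge
  notch <- circle_mask(H, W, c(70, 126), 14)
  tissue <- tissue_full & !notch
  arr <- he_canvas(H, W, c(255, 255, 255))
  arr <- he_fill(arr, tissue, HE_PINK)
  epi <- ring_mask(H, W, c(70, 126), 14, 22) & tissue
  fxhe <- rgb_image(arr)
  lum <- detect_incomplete_lumens(fxhe, binary_mask(tissue),
                                  binary_mask(epi))
  expect_length(lum, 1L)
  expect_false(lum[[1]]$complete)

  # same notch without epithelial lining: nothing
  lum2 <- detect_incomplete_lumens(fxhe, binary_mask(tissue),
                                   binary_mask(matrix(FALSE, H, W)))
  expect_length(lum2, 0L)
})

test_that("interior and edge lumens are attributed to the right detector", {
  H <- 160; W <- 160; ctr <- c(80, 80)
  notch <- circle_mask(H, W, c(80, 152), 22)
  tissue <- circle_mask(H, W, ctr, 66) & !notch
  inner <- circle_mask(H, W, c(80, 60), 10)
  arr <- he_canvas(H, W, c(255, 255, 255))
  arr <- he_fill(arr, tissue, HE_PINK)
  arr <- he_fill(arr, inner, HE_WHITE)
  epi <- (ring_mask(H, W, c(80, 60), 10, 17) |
            ring_mask(H, W, c(80, 152), 22, 30)) & tissue & !inner
  he <- rgb_image(arr)
  cl <- detect_complete_lumens(he, binary_mask(epi))
  il <- detect_incomplete_lumens(he, binary_mask(tissue & !inner),
                                 binary_mask(epi))
  expect_length(cl, 1L)
  expect_length(il, 1L)
})

test_that("degenerate tissue is an error for edge-lumen detection", {
  he <- rgb_image(he_canvas(30, 30, c(255, 255, 255)))
  tiny <- matrix(FALSE, 30, 30); tiny[15, 15] <- TRUE
  expect_error(detect_incomplete_lumens(he, binary_mask(tiny),
                                        binary_mask(tiny)),
               "degenerate")
})

# Nucleus fixtures ----------------------------------------------------------

nucleus_fixture <- function(centres, a = 6, b = 4, H = 100, W = 100) {
  arr <- he_canvas(H, W, HE_PINK)
  for (cc in centres) {
    ell <- outer(0:(H - 1), 0:(W - 1), function(r, c)
      ((c - cc[2]) / a)^2 + ((r - cc[1]) / b)^2 <= 1)
    arr <- he_fill(arr, ell, HE_BLUE)
  }
  rgb_image(arr)
}

test_that("a single dark ellipse on epithelium is one nucleus", {
  he <- nucleus_fixture(list(c(50, 50)))
  epi <- binary_mask(circle_mask(100, 100, c(50, 50), 25))
  nuc <- detect_nuclei(he, epi)
  expect_length(nuc, 1L)
  expect_lt(max(abs(nuc[[1]]$centroid - c(50, 50))), 1.5)
})

test_that("touching nuclei are split by the watershed", {
  he <- nucleus_fixture(list(c(50, 44), c(50, 56)))
  epi <- binary_mask(circle_mask(100, 100, c(50, 50), 30))
  nuc <- detect_nuclei(he, epi)
  expect_length(nuc, 2L)
  cents <- t(vapply(nuc, function(x) x$centroid, numeric(2)))
  # each detected component near one true centre
  d1 <- min(sqrt((cents[, 1] - 50)^2 + (cents[, 2] - 44)^2))
  d2 <- min(sqrt((cents[, 1] - 50)^2 + (cents[, 2] - 56)^2))
  expect_lt(d1, 4); expect_lt(d2, 4)
})

test_that("dark blobs outside the epithelium mask are ignored", {
  he <- nucleus_fixture(list(c(20, 20), c(70, 70)))
  epi <- binary_mask(circle_mask(100, 100, c(70, 70), 20))
  nuc <- detect_nuclei(he, epi)
  expect_length(nuc, 1L)
  expect_lt(max(abs(nuc[[1]]$centroid - c(70, 70))), 2)
})

test_that("segmentation output respects configured bounds", {
  smp <- render_sample(tissue_params("cancer", seed = 31))
  seg <- segment_sample(smp$pair)
  cfg <- seg_config()
  areas_n <- vapply(seg$nuclei, function(x) x$area_px, numeric(1))
  expect_true(all(areas_n >= cfg$min_nuc_area &
                    areas_n <= cfg$max_nuc_area))
  areas_l <- vapply(seg$lumens, function(x) x$area_px, numeric(1))
  expect_true(all(areas_l >= cfg$min_lumen_area))
  # no nucleus pixel outside the dilated epithelium mask
  br <- EBImage::makeBrush(2L * cfg$epi_dilate + 1L, "disc")
  epi_d <- as.matrix(EBImage::dilate(seg$epithelium_mask$mask * 1, br)) > 0.5
  for (nu in seg$nuclei) {
    ctr <- round(nu$centroid) + 1L
    expect_true(epi_d[ctr[1], ctr[2]])
  }
  # lumen pixels disjoint from the tissue mask
  for (l in seg$lumens)
    expect_false(any(seg$tissue_mask$mask[l$pixels + 1L]))
})

test_that("segmentation label masks round-trip through TIFF", {
  dir <- withr::local_tempdir()
  lum <- lumen_object(disc_pixels(6) + 10L)
  nuc <- nucleus_object(disc_pixels(3) + 30L)
  seg <- manual_seg(60, 60, lumens = list(lum), nuclei = list(nuc))
  paths <- write_segmentation_masks(seg, dir, "s1")
  lm <- round(tiff::readTIFF(paths[["lumens"]]) * 65535)
  expect_equal(sum(lm == 1), lum$area_px)
  nm <- round(tiff::readTIFF(paths[["nuclei"]]) * 65535)
  expect_equal(sum(nm == 1), nuc$area_px)
})
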