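# Lumen and nucleus segmentation on the H&E image, constrained by the
# registered epithelium map.
#
# Lumens are empty white spaces adjacent to epithelium-rich areas: complete
# lumens are interior white components fully inside the tissue; incomplete
# lumens are white components between the tissue boundary and the minimum
# enclosing circle of the sample, with crescent-shaped fitting artifacts
# rejected. Nuclei are dark elliptical bodies found by smoothing, adaptive
# histogram equalisation, an |R + G - B| colour score, adaptive
# thresholding inside epithelium, morphological closing and a
# distance-transform watershed, followed by size/shape/intensity filters.

#' Segmentation configuration
#'
#' All artifact-filter constants in one place. Areas are in pixels of the
#' H&E grid, distances in pixels.
#'
#' @param white_threshold channel intensity above which a pixel counts as
#'   white (all three channels must exceed it).
#' @param min_lumen_area,max_lumen_area lumen size bounds (px).
#' @param epi_adjacency_frac minimum fraction of a lumen's dilated boundary
#'   ring that must overlap epithelium.
#' @param min_solidity minimum area / convex-hull-area for complete lumens.
#' @param crescent_frac centroid-distance-to-circle-radius ratio above
#'   which an edge component is tested as a crescent artifact.
#' @param crescent_thickness_frac maximum radial thickness (fraction of the
#'   tissue-circle radius) for the thin-arc artifact test.
#' @param min_nuc_area,max_nuc_area nucleus size bounds (px).
#' @param max_ecc maximum nucleus eccentricity.
#' @param close_r disc radius of the morphological closing.
#' @param seed_sep minimum separation of watershed seeds (px).
#' @param sigma Gaussian smoothing sigma (px).
#' @param clahe_tile tile edge (px) for adaptive histogram equalisation.
#' @param clahe_limit contrast clip limit of the equaliser.
#' @param epi_dilate dilation radius applied to the epithelium mask when
#'   restricting nucleus candidates.
#' @param ring_w width of the dilated boundary ring used for adjacency and
#'   the lumen/cytoplasm association.
#' @param min_tissue minimum tissue pixels for edge-lumen detection.
#' @param intensity_reject reject nuclei whose mean colour score exceeds
#'   this; \code{NULL} uses the adaptive threshold itself.
#' @return a named list of constants.
#' @export
seg_config <- function(white_threshold = 200,
                       min_lumen_area = 30, max_lumen_area = 50000,
                       epi_adjacency_frac = 0.3, min_solidity = 0.7,
                       crescent_frac = 0.85, crescent_thickness_frac = 0.2,
                       min_nuc_area = 15, max_nuc_area = 500,
                       max_ecc = 0.97, close_r = 1, seed_sep = 3,
                       sigma = 1, clahe_tile = 64, clahe_limit = 2,
                       epi_dilate = 3, ring_w = 3, min_tissue = 50,
                       intensity_reject = NULL) {
  as.list(environment())
}

#' A segmented lumen
#'
#' @param pixels n x 2 matrix of 0-based (row, col) pixel coordinates.
#' @param complete TRUE for interior lumens, FALSE for edge lumens.
#' @return list with \code{pixels}, \code{area_px}, \code{perimeter_px},
#'   \code{centroid} (row, col) and \code{complete}.
#' @export
lumen_object <- function(pixels, complete = TRUE) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  structure(list(pixels = pixels, area_px = nrow(pixels),
                 perimeter_px = perimeter_crack(pixels),
                 centroid = c(mean(pixels[, 1]), mean(pixels[, 2])),
                 complete = isTRUE(complete)),
            class = "lumen_object")
}

#' A segmented nucleus
#'
#' @param pixels n x 2 matrix of 0-based (row, col) pixel coordinates.
#' @param mean_intensity mean colour score of the nucleus pixels.
#' @return list with \code{pixels}, \code{area_px}, \code{centroid} and
#'   \code{mean_intensity}.
#' @export
nucleus_object <- function(pixels, mean_intensity = NA_real_) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  structure(list(pixels = pixels, area_px = nrow(pixels),
                 centroid = c(mean(pixels[, 1]), mean(pixels[, 2])),
                 mean_intensity = mean_intensity),
            class = "nucleus_object")
}

#' Map the registered epithelium label onto the H&E grid
#'
#' @param pair \code{\link{sample_pair}}.
#' @param reg \code{registration_result} from \code{\link{register_pair}}
#'   (parameters on the H&E grid).
#' @return \code{\link{binary_mask}} on the H&E grid, TRUE where the
#'   transformed label equals epithelium.
#' @export
epithelium_mask_from_ir <- function(pair, reg) {
  epi <- pair$ir$labels == IR_LABELS[["epithelium"]]
  # pivot about the full tissue footprint, matching how the registration
  # parameters were fitted
  ctr <- mask_centroid_xy(binarize_ir(pair$ir)$mask)
  binary_mask(apply_affine_with_pivot(epi, reg$params,
                                      dim(pair$he$pixels)[1:2], ctr))
}

# Split a label matrix into a list of 0-based (row, col) pixel matrices.
split_label_pixels <- function(lab) {
  idx <- which(lab > 0.5, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  lv <- lab[idx]
  lapply(split(seq_len(nrow(idx)), lv),
         function(i) cbind(idx[i, 1] - 1L, idx[i, 2] - 1L))
}

# Boundary ring of a component: dilation by `ring_w` minus the component,
# computed on a padded bounding box. Returns 1-based full-image indices.
component_ring <- function(pixels, shape, ring_w = 3) {
  pad <- ring_w + 1L
  pm <- px_to_mask(pixels, pad = pad)
  br <- EBImage::makeBrush(2L * ring_w + 1L, "disc")
  dil <- as.matrix(EBImage::dilate(pm$mask * 1, br)) > 0.5
  ring <- which(dil & !pm$mask, arr.ind = TRUE)
  r <- ring[, 1] - 1L + pm$off[1]
  c <- ring[, 2] - 1L + pm$off[2]
  ok <- r >= 0L & r < shape[1] & c >= 0L & c < shape[2]
  cbind(r[ok] + 1L, c[ok] + 1L)
}

# Fraction of a component's boundary ring overlapping a mask.
ring_fraction <- function(pixels, mask, ring_w = 3) {
  ring <- component_ring(pixels, dim(mask), ring_w)
  if (nrow(ring) == 0L) return(0)
  mean(mask[ring])
}

# Labels of white components touching the image border.
border_labels <- function(lab) {
  b <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  setdiff(unique(b), 0)
}

#' Detect complete lumens
#'
#' Connected white components strictly inside the tissue are retained when
#' their dilated boundary ring overlaps epithelium by at least
#' \code{cfg$epi_adjacency_frac}, their area lies within the configured
#' bounds, and their solidity passes \code{cfg$min_solidity}.
#'
#' @param he \code{\link{rgb_image}}.
#' @param epi epithelium \code{\link{binary_mask}} on the H&E grid.
#' @param cfg \code{\link{seg_config}}.
#' @return list of \code{\link{lumen_object}} with \code{complete = TRUE}.
#' @export
detect_complete_lumens <- function(he, epi, cfg = seg_config()) {
  epim <- if (inherits(epi, "binary_mask")) epi$mask else epi
  white <- white_mask_he(he, cfg$white_threshold)
  lab <- as.matrix(EBImage::bwlabel(white * 1L))
  drop <- border_labels(lab)   # background / edge components
  lab[lab %in% drop] <- 0L
  comps <- split_label_pixels(lab)
  out <- list()
  for (px in comps) {
    a <- nrow(px)
    if (a < cfg$min_lumen_area || a > cfg$max_lumen_area) next
    if (a / hull_area_px(px) < cfg$min_solidity) next
    if (ring_fraction(px, epim, cfg$ring_w) < cfg$epi_adjacency_frac) next
    out[[length(out) + 1L]] <- lumen_object(px, complete = TRUE)
  }
  out
}

#' Minimum enclosing circle of the tissue mask
#'
#' @param tissue \code{\link{binary_mask}}.
#' @return list(center = (x, y) in 0-based pixel coordinates, radius).
#' @export
tissue_circle <- function(tissue) {
  m <- if (inherits(tissue, "binary_mask")) tissue$mask else tissue
  idx <- which(boundary_mask(m), arr.ind = TRUE)
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  min_enclosing_circle_pts(pts)
}

#' Detect incomplete lumens at the tissue edge
#'
#' Models the tissue sample as its minimum enclosing circle; white
#' components between the tissue boundary and the circle that touch the
#' tissue edge are candidates, filtered by size and epithelial adjacency.
#' Crescent-shaped gaps between the tissue outline and the fitted circle
#' are rejected when the component centroid sits near the circle rim
#' (distance/radius > \code{cfg$crescent_frac}) and the component is a
#' thin arc (radial thickness below \code{cfg$crescent_thickness_frac} of
#' the radius).
#'
#' @param he \code{\link{rgb_image}}.
#' @param tissue tissue \code{\link{binary_mask}}.
#' @param epi epithelium \code{\link{binary_mask}}.
#' @param cfg \code{\link{seg_config}}.
#' @return list of \code{\link{lumen_object}} with \code{complete = FALSE}.
#' @export
detect_incomplete_lumens <- function(he, tissue, epi, cfg = seg_config()) {
  tm <- if (inherits(tissue, "binary_mask")) tissue$mask else tissue
  epim <- if (inherits(epi, "binary_mask")) epi$mask else epi
  if (sum(tm) < cfg$min_tissue)
    stop("detect_incomplete_lumens: degenerate tissue mask (< ",
         cfg$min_tissue, " px)")
  circ <- tissue_circle(tm)
  H <- nrow(tm); W <- ncol(tm)
  xo <- matrix(rep(0:(W - 1), each = H), H, W)
  yo <- matrix(rep(0:(H - 1), times = W), H, W)
  inside <- (xo - circ$center[1])^2 + (yo - circ$center[2])^2 <=
    circ$radius^2
  white <- white_mask_he(he, cfg$white_threshold)
  labw <- as.matrix(EBImage::bwlabel(white * 1L))
  outer_ids <- border_labels(labw)
  cand <- white & inside & (matrix(labw %in% outer_ids, H, W))
  lab <- as.matrix(EBImage::bwlabel(cand * 1L))
  comps <- split_label_pixels(lab)
  out <- list()
  for (px in comps) {
    a <- nrow(px)
    if (a < cfg$min_lumen_area || a > cfg$max_lumen_area) next
    ring <- component_ring(px, dim(tm), cfg$ring_w)
    if (nrow(ring) == 0L || !any(tm[ring])) next       # must touch tissue
    if (mean(epim[ring]) < cfg$epi_adjacency_frac) next
    d <- sqrt((px[, 2] - circ$center[1])^2 + (px[, 1] - circ$center[2])^2)
    ctd <- sqrt((mean(px[, 2]) - circ$center[1])^2 +
                  (mean(px[, 1]) - circ$center[2])^2)
    thin <- (max(d) - min(d)) <= cfg$crescent_thickness_frac * circ$radius
    if (ctd / circ$radius > cfg$crescent_frac && thin) next
    out[[length(out) + 1L]] <- lumen_object(px, complete = FALSE)
  }
  out
}

# Otsu threshold on a numeric vector (maximise between-class variance over
# a fixed-bin histogram).
otsu_thresh <- function(v, bins = 256L, range = NULL) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NA_real_)
  if (is.null(range)) range <- range(v)
  if (diff(range) == 0) return(range[1])
  br <- seq(range[1], range[2], length.out = bins + 1L)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), nbins = bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p); w1 <- 1 - w0
  mu <- cumsum(p * mids); mu_t <- mu[bins]
  bc <- (mu_t * w0 - mu)^2 / (w0 * w1)
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

#' Detect epithelial nuclei
#'
#' Pipeline: Gaussian smoothing, contrast-limited adaptive histogram
#' equalisation, per-pixel colour score |R + G - B| (low on blue nuclei,
#' high on pink cytoplasm and white lumens), adaptive (Otsu) threshold on
#' the within-epithelium score histogram, morphological closing, a
#' distance-transform watershed to split touching nuclei, and rejection of
#' components by area, eccentricity, mean score and epithelium membership.
#'
#' @param he \code{\link{rgb_image}}.
#' @param epi epithelium \code{\link{binary_mask}} on the H&E grid; must be
#'   nonempty.
#' @param cfg \code{\link{seg_config}}.
#' @return list of \code{\link{nucleus_object}}.
#' @export
detect_nuclei <- function(he, epi, cfg = seg_config()) {
  epim <- if (inherits(epi, "binary_mask")) epi$mask else epi
  if (!any(epim)) stop("detect_nuclei: empty epithelium mask")
  p <- he$pixels / 255
  chans <- lapply(1:3, function(k) {
    ch <- EBImage::gblur(p[, , k], sigma = cfg$sigma)
    nx <- max(2L, round(ncol(ch) / cfg$clahe_tile))
    ny <- max(2L, round(nrow(ch) / cfg$clahe_tile))
    eq <- try(EBImage::clahe(ch, nx = nx, ny = ny, limit = cfg$clahe_limit,
                             keep.range = TRUE), silent = TRUE)
    if (inherits(eq, "try-error")) ch else as.matrix(eq)
  })
  score <- abs(chans[[1]] + chans[[2]] - chans[[3]])   # low on nuclei
  br <- EBImage::makeBrush(2L * cfg$epi_dilate + 1L, "disc")
  epi_d <- as.matrix(EBImage::dilate(epim * 1, br)) > 0.5
  cut <- otsu_thresh(score[epi_d], range = c(0, 2))
  reject_cut <- if (is.null(cfg$intensity_reject)) cut else cfg$intensity_reject
  nucmask <- (score < cut) & epi_d
  kern <- EBImage::makeBrush(2L * cfg$close_r + 1L, "disc")
  nucmask <- as.matrix(EBImage::closing(nucmask * 1, kern)) > 0.5
  nucmask <- as.matrix(EBImage::fillHull(nucmask * 1)) > 0.5
  dm <- EBImage::distmap(nucmask * 1)
  ws <- as.matrix(EBImage::watershed(dm, tolerance = 1, ext = cfg$seed_sep))
  comps <- split_label_pixels(ws)
  ecc <- tryCatch(EBImage::computeFeatures.moment(ws)[, "m.eccentricity"],
                  error = function(e) NULL)
  out <- list()
  for (i in seq_along(comps)) {
    px <- comps[[i]]
    a <- nrow(px)
    if (a < cfg$min_nuc_area || a > cfg$max_nuc_area) next
    if (!is.null(ecc) && length(ecc) >= i && is.finite(ecc[i]) &&
        ecc[i] > cfg$max_ecc) next
    ms <- mean(score[px + 1L])
    if (ms > reject_cut) next
    ctr <- round(c(mean(px[, 1]), mean(px[, 2]))) + 1L
    # centroid must lie in the (dilated) epithelium restriction mask; the
    # dilation absorbs the half-label-pixel quantisation of the mapped mask
    if (!epi_d[ctr[1], ctr[2]]) next
    out[[length(out) + 1L]] <- nucleus_object(px, mean_intensity = ms)
  }
  out
}

#' Write segmentation label masks as TIFF
#'
#' One 16-bit label raster per object class (lumens, nuclei): pixel value
#' 0 is background, k the k-th object.
#'
#' @param seg \code{segmentation_result}.
#' @param dir output directory.
#' @param id sample identifier used in the file names.
#' @return paths of the written files, invisibly.
#' @export
write_segmentation_masks <- function(seg, dir, id = "sample") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shape <- dim(seg$tissue_mask$mask)
  render <- function(objs) {
    m <- matrix(0L, shape[1], shape[2])
    for (k in seq_along(objs)) m[objs[[k]]$pixels + 1L] <- k
    m
  }
  paths <- c(lumens = file.path(dir, paste0(id, "_lumens.tif")),
             nuclei = file.path(dir, paste0(id, "_nuclei.tif")))
  tiff::writeTIFF(render(seg$lumens) / 65535, paths[["lumens"]],
                  bits.per.sample = 16L)
  tiff::writeTIFF(render(seg$nuclei) / 65535, paths[["nuclei"]],
                  bits.per.sample = 16L)
  invisible(paths)
}

#' Segment one sample end to end
#'
#' @param pair \code{\link{sample_pair}}.
#' @param reg \code{registration_result} on the H&E grid; \code{NULL} runs
#'   \code{\link{register_pair}} first.
#' @param cfg \code{\link{seg_config}}.
#' @return object of class \code{segmentation_result}: \code{lumens},
#'   \code{nuclei}, \code{epithelium_mask}, \code{tissue_mask},
#'   \code{tissue_circle}, \code{registration}.
#' @export
segment_sample <- function(pair, reg = NULL, cfg = seg_config()) {
  if (is.null(reg)) reg <- register_pair(pair, cfg$white_threshold)
  epi <- epithelium_mask_from_ir(pair, reg)
  tissue <- binarize_he(pair$he, cfg$white_threshold)
  lum_c <- detect_complete_lumens(pair$he, epi, cfg)
  lum_i <- if (sum(tissue$mask) >= cfg$min_tissue)
    detect_incomplete_lumens(pair$he, tissue, epi, cfg) else list()
  nuclei <- if (any(epi$mask)) detect_nuclei(pair$he, epi, cfg) else list()
  structure(list(lumens = c(lum_c, lum_i), nuclei = nuclei,
                 epithelium_mask = epi, tissue_mask = tissue,
                 tissue_circle = tissue_circle(tissue),
                 registration = reg),
            class = "segmentation_result")
}
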