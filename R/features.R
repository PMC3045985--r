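# Morphological feature extraction.
#
# Seventeen categories of epithelium- and lumen-related quantities are
# summarised into 67 features: 29 global (AVG/STD/TOT over the whole
# sample) and 38 local (STD/MIN/MAX over sliding-window summaries). The
# category-to-aggregator assignment below is the package's documented
# default and can be swapped via a registry file.

FEATURE_CATEGORIES <- c(
  "epithelium_area", "nucleus_area", "nucleus_count",
  "nucleus_lumen_dist", "nucleus_epiboundary_dist",
  "isolated_nucleus_count", "far_nucleus_count", "nucleus_spatial_entropy",
  "lumen_area", "lumen_count", "lumen_roundness", "lumen_distortion",
  "lumen_mbc_ratio", "lumen_convex_ratio", "lumen_boundary_symmetry",
  "lumen_area_symmetry", "lumen_cytoplasm_assoc")

#' The default 67-feature registry
#'
#' 29 global and 38 local features over 17 quantity categories. Global
#' aggregators are AVG/STD and, for counts and sizes, TOT. Local features
#' summarise a 100 x 100 px sliding window: the within-window statistic
#' (AVG, TOT, or the value itself for per-window scalars, VAL) is reduced
#' over all window positions by STD, MIN or MAX.
#'
#' @return data.frame with columns \code{feature_id}, \code{category}
#'   (1..17), \code{category_name}, \code{scope} (global/local),
#'   \code{aggregator}, \code{window_stat}.
#' @export
feature_registry <- function() {
  g <- list(  # category index -> global aggregators
    `1` = "TOT", `2` = c("AVG", "STD", "TOT"), `3` = "TOT",
    `4` = c("AVG", "STD"), `5` = c("AVG", "STD"), `6` = "TOT",
    `7` = "TOT", `8` = "AVG", `9` = c("AVG", "STD", "TOT"), `10` = "TOT",
    `11` = c("AVG", "STD"), `12` = c("AVG", "STD"), `13` = c("AVG", "STD"),
    `14` = c("AVG", "STD"), `15` = c("AVG", "STD"), `16` = c("AVG", "STD"),
    `17` = "AVG")
  l <- list(  # category index -> list(window_stat, outer stats)
    `1` = list("TOT", c("STD", "MAX")),
    `2` = list("AVG", c("STD", "MIN", "MAX")),
    `3` = list("TOT", c("STD", "MAX")),
    `4` = list("AVG", c("STD", "MIN", "MAX")),
    `5` = list("AVG", c("STD", "MAX")),
    `6` = list("TOT", c("STD", "MAX")),
    `7` = list("TOT", c("STD", "MAX")),
    `8` = list("VAL", c("STD", "MIN")),
    `9` = list("TOT", c("STD", "MIN", "MAX")),
    `10` = list("TOT", c("STD", "MAX")),
    `11` = list("AVG", c("STD", "MIN", "MAX")),
    `12` = list("AVG", c("STD", "MAX")),
    `13` = list("AVG", c("STD", "MAX")),
    `14` = list("AVG", c("STD", "MAX")),
    `15` = list("AVG", c("STD", "MAX")),
    `16` = list("AVG", c("STD", "MAX")),
    `17` = list("AVG", c("STD", "MAX")))
  rows <- list()
  for (k in 1:17) {
    nm <- FEATURE_CATEGORIES[k]
    for (a in g[[as.character(k)]])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0("G_", a, "_", nm), category = k,
        category_name = nm, scope = "global", aggregator = a,
        window_stat = NA_character_)
    spec <- l[[as.character(k)]]
    for (a in spec[[2]])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0("L_", a, "_", nm), category = k,
        category_name = nm, scope = "local", aggregator = a,
        window_stat = spec[[1]])
  }
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  reg
}

#' Validate a feature registry
#'
#' @param reg registry data.frame.
#' @return the registry, invisibly; errors if the counts (67 total, 29
#'   global, 38 local, all 17 categories represented) are violated.
#' @export
validate_registry <- function(reg) {
  stopifnot(nrow(reg) == 67L,
            sum(reg$scope == "global") == 29L,
            sum(reg$scope == "local") == 38L,
            setequal(unique(reg$category), 1:17),
            !anyDuplicated(reg$feature_id))
  invisible(reg)
}

#' Write / read a feature registry as JSON
#'
#' @param reg registry data.frame.
#' @param path JSON file path.
#' @return \code{read_registry} returns the registry data.frame.
#' @export
write_registry <- function(reg, path) {
  jsonlite::write_json(list(version = 1L, entries = reg), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- as.data.frame(x$entries)
  reg$window_stat[reg$window_stat == ""] <- NA_character_
  validate_registry(reg)
  reg
}

#' Feature-extraction configuration
#'
#' @param isolation_dist a nucleus with no neighbouring nucleus centroid
#'   within this distance (px) counts as isolated.
#' @param far_dist nuclei farther than this (px) from any lumen count as
#'   "far from lumens".
#' @param entropy_grid side of the g x g grid for the global spatial
#'   entropy of nucleus centroids.
#' @param entropy_grid_local grid side for the per-window entropy.
#' @param window sliding-window edge (px).
#' @param stride window stride (px); the default gives half-overlap.
#' @param min_cover windows with tissue coverage below this fraction are
#'   excluded.
#' @param ring_w ring width for the lumen/cytoplasm association.
#' @return named list.
#' @export
feat_config <- function(isolation_dist = 30, far_dist = 80,
                        entropy_grid = 8, entropy_grid_local = 4,
                        window = 100, stride = 50, min_cover = 0.2,
                        ring_w = 3) {
  as.list(environment())
}

#' Lumen roundness
#'
#' \code{L_peri^2 / (L_area * r)} with \code{r = sqrt(L_area / pi)},
#' applied literally; note this is scale-dependent (a perfect disc of
#' radius R gives \code{4 * pi / R}).
#'
#' @param l \code{\link{lumen_object}}.
#' @return positive real.
#' @export
lumen_roundness <- function(l) {
  l$perimeter_px^2 / (l$area_px * sqrt(l$area_px / pi))
}

#' Lumen distortion
#'
#' Coefficient of variation (STD/AVG) of the distances from the lumen
#' centroid to its boundary pixels; 0 for a perfect disc and for
#' degenerate single-pixel objects.
#'
#' @param l \code{\link{lumen_object}}.
#' @return nonnegative real.
#' @export
lumen_distortion <- function(l) {
  b <- boundary_pixels(l$pixels)
  d <- sqrt((b[, 1] - l$centroid[1])^2 + (b[, 2] - l$centroid[2])^2)
  m <- mean(d)
  if (length(d) < 2L || m == 0) return(0)
  sd(d) / m
}

#' Lumen minimum-bounding-circle ratio
#'
#' Area of the minimum enclosing circle of the lumen's pixels (over pixel
#' corners) divided by the lumen area. Always >= 1.
#'
#' @param l \code{\link{lumen_object}}.
#' @return real >= 1.
#' @export
lumen_mbc_ratio <- function(l) {
  mec <- min_enclosing_circle(l$pixels)
  pi * mec$radius^2 / l$area_px
}

#' Lumen convex hull ratio
#'
#' Convex-hull area (over pixel corners) divided by the lumen area.
#' Always >= 1, equal to 1 for convex shapes up to rasterisation.
#'
#' @param l \code{\link{lumen_object}}.
#' @return real >= 1.
#' @export
lumen_convex_ratio <- function(l) {
  hull_area_px(l$pixels) / l$area_px
}

# Reflect 0-based (row, col) pixels across the line through `centre`
# (row, col) with direction `axis` ((x, y) unit vector), rounding back to
# the grid.
reflect_pixels <- function(pixels, centre, axis) {
  vx <- axis[1]; vy <- axis[2]
  # reflection matrix 2vv' - I in (x, y)
  dx <- pixels[, 2] - centre[2]
  dy <- pixels[, 1] - centre[1]
  rx <- (2 * vx * vx - 1) * dx + 2 * vx * vy * dy
  ry <- 2 * vx * vy * dx + (2 * vy * vy - 1) * dy
  cbind(round(centre[1] + ry), round(centre[2] + rx))
}

# Encode (row, col) pixels as single keys for set arithmetic.
px_key <- function(pixels) pixels[, 1] * 10000000 + pixels[, 2]

#' Lumen symmetry indices
#'
#' Surrogate symmetry measures: the pixel set (and its boundary pixel set)
#' are reflected across the principal axis through the centroid;
#' \code{boundary_sym} is the symmetric difference of the boundary pixel
#' sets over the summed boundary lengths, \code{area_sym} the symmetric
#' difference of the areas over twice the area. Both lie in [0, 1] with 0
#' for perfect mirror symmetry.
#'
#' @param l \code{\link{lumen_object}}.
#' @return named numeric: \code{boundary_sym}, \code{area_sym}.
#' @export
lumen_symmetry_indices <- function(l) {
  ax <- principal_axis(l$pixels)
  ctr <- l$centroid
  a <- px_key(l$pixels)
  ar <- px_key(reflect_pixels(l$pixels, ctr, ax))
  area_sym <- (length(setdiff(a, ar)) + length(setdiff(ar, a))) /
    (2 * l$area_px)
  b <- boundary_pixels(l$pixels)
  bk <- px_key(b)
  brk <- px_key(reflect_pixels(b, ctr, ax))
  boundary_sym <- (length(setdiff(bk, brk)) + length(setdiff(brk, bk))) /
    (length(bk) + length(brk))
  c(boundary_sym = boundary_sym, area_sym = area_sym)
}

#' Spatial association of a lumen with cytoplasm-rich epithelium
#'
#' Fraction of the lumen's dilated boundary ring occupied by epithelial
#' pixels whose colour classifies them as cytoplasm-rich (pink, R > B)
#' rather than nuclear (B >= R).
#'
#' @param l \code{\link{lumen_object}}.
#' @param he \code{\link{rgb_image}}.
#' @param epi epithelium \code{\link{binary_mask}}.
#' @param cfg \code{\link{feat_config}}.
#' @return real in [0, 1].
#' @export
lumen_cytoplasm_association <- function(l, he, epi, cfg = feat_config()) {
  epim <- if (inherits(epi, "binary_mask")) epi$mask else epi
  ring <- component_ring(l$pixels, dim(epim), cfg$ring_w)
  if (nrow(ring) == 0L) return(0)
  r <- he$pixels[, , 1][ring]; b <- he$pixels[, , 3][ring]
  mean(epim[ring] & (r > b))
}

# Shannon entropy of counts normalised by log of the occupied-cell
# capacity (the number of cells that could be occupied).
norm_entropy <- function(counts, capacity) {
  n <- sum(counts)
  if (n <= 1L || capacity < 2) return(0)
  p <- counts[counts > 0] / n
  h <- -sum(p * log(p))
  h / log(max(2, min(capacity, n)))
}

# Spatial entropy of centroids over a g x g grid spanning `bbox`
# (rmin, rmax, cmin, cmax); capacity = number of grid cells intersecting
# the tissue mask (restricted to the bbox).
spatial_entropy <- function(centroids, bbox, g, tissue = NULL) {
  if (is.null(centroids) || nrow(centroids) == 0L) return(0)
  rb <- seq(bbox[1], bbox[2] + 1e-9, length.out = g + 1L)
  cb <- seq(bbox[3], bbox[4] + 1e-9, length.out = g + 1L)
  ri <- pmin(pmax(findInterval(centroids[, 1], rb, all.inside = TRUE), 1), g)
  ci <- pmin(pmax(findInterval(centroids[, 2], cb, all.inside = TRUE), 1), g)
  counts <- tabulate((ri - 1L) * g + ci, nbins = g * g)
  capacity <- g * g
  if (!is.null(tissue)) {
    occ <- 0L
    for (i in seq_len(g)) for (j in seq_len(g)) {
      rr <- max(1L, ceiling(rb[i] + 1)):min(nrow(tissue), floor(rb[i + 1] + 1))
      cc <- max(1L, ceiling(cb[j] + 1)):min(ncol(tissue), floor(cb[j + 1] + 1))
      if (length(rr) && length(cc) && any(tissue[rr, cc])) occ <- occ + 1L
    }
    capacity <- max(occ, 1L)
  }
  norm_entropy(counts, capacity)
}

#' Epithelium-related quantities of a segmented sample
#'
#' Computes the eight epithelial quantities: total epithelium area,
#' per-nucleus areas, nucleus count, per-nucleus distance to the nearest
#' lumen, per-nucleus distance to the epithelium boundary, isolated-nucleus
#' flags, far-from-lumen flags, and the normalised spatial entropy of the
#' nucleus centroids.
#'
#' @param seg \code{segmentation_result}.
#' @param cfg \code{\link{feat_config}}.
#' @return named list of quantities (vectors are per nucleus).
#' @export
epithelium_quantities <- function(seg, cfg = feat_config()) {
  epim <- seg$epithelium_mask$mask
  tism <- seg$tissue_mask$mask
  nuc <- seg$nuclei
  n <- length(nuc)
  areas <- vapply(nuc, function(x) x$area_px, numeric(1))
  cent <- if (n) t(vapply(nuc, function(x) x$centroid, numeric(2)))
          else matrix(numeric(0), 0, 2)
  # distance from each nucleus centroid to the nearest lumen pixel
  lmask <- matrix(FALSE, nrow(epim), ncol(epim))
  for (l in seg$lumens) lmask[l$pixels + 1L] <- TRUE
  if (any(lmask) && n) {
    dmap <- as.matrix(EBImage::distmap((!lmask) * 1))
    idx <- cbind(pmin(pmax(round(cent[, 1]) + 1L, 1L), nrow(lmask)),
                 pmin(pmax(round(cent[, 2]) + 1L, 1L), ncol(lmask)))
    d_lumen <- dmap[idx]
  } else d_lumen <- rep(NA_real_, n)
  # distance to the epithelium-mask boundary (distance transform inside)
  if (any(epim) && n) {
    emap <- as.matrix(EBImage::distmap(epim * 1))
    idx <- cbind(pmin(pmax(round(cent[, 1]) + 1L, 1L), nrow(epim)),
                 pmin(pmax(round(cent[, 2]) + 1L, 1L), ncol(epim)))
    d_epib <- emap[idx]
  } else d_epib <- rep(NA_real_, n)
  isolated <- logical(n)
  if (n > 1L) {
    dd <- as.matrix(dist(cent))
    diag(dd) <- Inf
    isolated <- apply(dd, 1, min) > cfg$isolation_dist
  } else if (n == 1L) isolated <- TRUE
  far <- !is.na(d_lumen) & d_lumen > cfg$far_dist
  idxt <- which(tism, arr.ind = TRUE)
  bbox <- if (nrow(idxt)) c(min(idxt[, 1]) - 1, max(idxt[, 1]) - 1,
                            min(idxt[, 2]) - 1, max(idxt[, 2]) - 1)
          else c(0, nrow(tism) - 1, 0, ncol(tism) - 1)
  ent <- spatial_entropy(cent, bbox, cfg$entropy_grid, tissue = tism)
  list(epithelium_area = sum(epim), nucleus_areas = areas,
       nucleus_count = n, nucleus_lumen_dist = d_lumen,
       nucleus_epiboundary_dist = d_epib, isolated = isolated, far = far,
       spatial_entropy = ent, centroids = cent)
}

# Per-lumen shape quantity table.
lumen_quantities <- function(seg, he, cfg = feat_config()) {
  ls <- seg$lumens
  n <- length(ls)
  if (n == 0L)
    return(data.frame(area = numeric(0), roundness = numeric(0),
                      distortion = numeric(0), mbc = numeric(0),
                      convex = numeric(0), bsym = numeric(0),
                      asym = numeric(0), cyto = numeric(0),
                      crow = numeric(0), ccol = numeric(0)))
  sym <- t(vapply(ls, lumen_symmetry_indices, numeric(2)))
  data.frame(
    area = vapply(ls, function(l) l$area_px, numeric(1)),
    roundness = vapply(ls, lumen_roundness, numeric(1)),
    distortion = vapply(ls, lumen_distortion, numeric(1)),
    mbc = vapply(ls, lumen_mbc_ratio, numeric(1)),
    convex = vapply(ls, lumen_convex_ratio, numeric(1)),
    bsym = sym[, 1], asym = sym[, 2],
    cyto = vapply(ls, function(l)
      lumen_cytoplasm_association(l, he, seg$epithelium_mask, cfg),
      numeric(1)),
    crow = vapply(ls, function(l) l$centroid[1], numeric(1)),
    ccol = vapply(ls, function(l) l$centroid[2], numeric(1)))
}

# Aggregate a vector for a global feature. Empty vectors: TOT -> 0 (a true
# zero total), AVG/STD -> NA (handled by the missing policy); single
# values: STD -> 0.
agg_global <- function(v, stat) {
  v <- v[is.finite(v)]
  if (stat == "TOT") return(if (length(v)) sum(v) else 0)
  if (length(v) == 0L) return(NA_real_)
  switch(stat,
         AVG = mean(v),
         STD = if (length(v) < 2L) 0 else sd(v),
         MIN = min(v), MAX = max(v))
}

#' Extract the 67-feature vector of a segmented sample
#'
#' Global features aggregate per-object quantities over the whole sample;
#' local features reduce within-window statistics (100 x 100 px window)
#' over all window positions by STD/MIN/MAX. Windows with insufficient
#' tissue coverage are excluded. Samples lacking lumens (or any valid
#' windows) receive the neutral sentinel 0 for the affected features and
#' the vector is flagged via \code{missing_policy_applied}.
#'
#' @param seg \code{segmentation_result}.
#' @param he \code{\link{rgb_image}}.
#' @param registry registry data.frame from \code{\link{feature_registry}}.
#' @param cfg \code{\link{feat_config}}.
#' @param sample_id identifier recorded on the vector.
#' @return object of class \code{feature_vector}: \code{sample_id},
#'   \code{values} (named 67-vector), \code{missing_policy_applied}.
#' @export
extract_features <- function(seg, he, registry = feature_registry(),
                             cfg = feat_config(), sample_id = "sample") {
  validate_registry(registry)
  eq <- epithelium_quantities(seg, cfg)
  lq <- lumen_quantities(seg, he, cfg)
  tism <- seg$tissue_mask$mask
  lmask <- matrix(FALSE, nrow(tism), ncol(tism))
  for (l in seg$lumens) lmask[l$pixels + 1L] <- TRUE
  epim <- seg$epithelium_mask$mask

  glob_vec <- function(k) switch(as.character(k),
    `1` = eq$epithelium_area,
    `2` = eq$nucleus_areas,
    `3` = eq$nucleus_count,
    `4` = eq$nucleus_lumen_dist,
    `5` = eq$nucleus_epiboundary_dist,
    `6` = sum(eq$isolated),
    `7` = sum(eq$far),
    `8` = eq$spatial_entropy,
    `9` = lq$area,
    `10` = nrow(lq),
    `11` = lq$roundness, `12` = lq$distortion, `13` = lq$mbc,
    `14` = lq$convex, `15` = lq$bsym, `16` = lq$asym, `17` = lq$cyto)

  # window grid
  H <- nrow(tism); W <- ncol(tism)
  wrows <- if (H >= cfg$window) seq(0L, H - cfg$window, by = cfg$stride)
           else integer(0)
  wcols <- if (W >= cfg$window) seq(0L, W - cfg$window, by = cfg$stride)
           else integer(0)
  nc <- eq$centroids
  win_vals <- vector("list", 17)
  for (k in 1:17) win_vals[[k]] <- numeric(0)
  for (r0 in wrows) for (c0 in wcols) {
    rr <- (r0 + 1L):(r0 + cfg$window)
    cc <- (c0 + 1L):(c0 + cfg$window)
    if (mean(tism[rr, cc]) < cfg$min_cover) next
    in_win_n <- if (nrow(nc)) nc[, 1] >= r0 & nc[, 1] < r0 + cfg$window &
                              nc[, 2] >= c0 & nc[, 2] < c0 + cfg$window
                else logical(0)
    in_win_l <- if (nrow(lq)) lq$crow >= r0 & lq$crow < r0 + cfg$window &
                              lq$ccol >= c0 & lq$ccol < c0 + cfg$window
                else logical(0)
    wv <- list(
      `1` = sum(epim[rr, cc]),
      `2` = if (any(in_win_n)) mean(eq$nucleus_areas[in_win_n]) else NA,
      `3` = sum(in_win_n),
      `4` = { d <- eq$nucleus_lumen_dist[in_win_n]
              d <- d[is.finite(d)]; if (length(d)) mean(d) else NA },
      `5` = { d <- eq$nucleus_epiboundary_dist[in_win_n]
              d <- d[is.finite(d)]; if (length(d)) mean(d) else NA },
      `6` = sum(eq$isolated[in_win_n]),
      `7` = sum(eq$far[in_win_n]),
      `8` = spatial_entropy(nc[in_win_n, , drop = FALSE],
                            c(r0, r0 + cfg$window - 1, c0,
                              c0 + cfg$window - 1),
                            cfg$entropy_grid_local),
      `9` = sum(lmask[rr, cc]),   # partial lumen area within the window
      `10` = sum(in_win_l),
      `11` = if (any(in_win_l)) mean(lq$roundness[in_win_l]) else NA,
      `12` = if (any(in_win_l)) mean(lq$distortion[in_win_l]) else NA,
      `13` = if (any(in_win_l)) mean(lq$mbc[in_win_l]) else NA,
      `14` = if (any(in_win_l)) mean(lq$convex[in_win_l]) else NA,
      `15` = if (any(in_win_l)) mean(lq$bsym[in_win_l]) else NA,
      `16` = if (any(in_win_l)) mean(lq$asym[in_win_l]) else NA,
      `17` = if (any(in_win_l)) mean(lq$cyto[in_win_l]) else NA)
    for (k in 1:17)
      win_vals[[k]] <- c(win_vals[[k]], wv[[as.character(k)]])
  }

  vals <- numeric(nrow(registry))
  names(vals) <- registry$feature_id
  missing_applied <- FALSE
  for (i in seq_len(nrow(registry))) {
    row <- registry[i, ]
    if (row$scope == "global") {
      x <- agg_global(glob_vec(row$category), row$aggregator)
    } else {
      wv <- win_vals[[row$category]]
      x <- agg_global(wv, row$aggregator)
    }
    if (is.na(x)) { x <- 0; missing_applied <- TRUE }
    vals[i] <- x
  }
  structure(list(sample_id = sample_id, values = vals,
                 missing_policy_applied = missing_applied),
            class = "feature_vector")
}

#' Assemble feature vectors into a cohort matrix
#'
#' @param fvs list of \code{feature_vector} objects.
#' @param labels optional vector of class labels (0/1) per sample.
#' @return data.frame with \code{sample_id}, one column per feature, and a
#'   \code{label} column when labels are given.
#' @export
feature_table <- function(fvs, labels = NULL) {
  X <- do.call(rbind, lapply(fvs, function(f) f$values))
  df <- data.frame(sample_id = vapply(fvs, function(f) f$sample_id,
                                      character(1)),
                   X, check.names = FALSE)
  if (!is.null(labels)) df$label <- labels
  df
}
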