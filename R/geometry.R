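# Raster geometry helpers: boundary extraction, perimeter estimation,
# convex hulls and minimum enclosing circles on pixel sets.
#
# Pixel sets are n x 2 integer matrices of 0-based (row, col) centres.

# Build a padded logical matrix from a pixel set; returns the mask plus the
# (row, col) offset such that mask[r, c] corresponds to pixel
# (r - 1 - pad + off_r, c - 1 - pad + off_c) in 0-based image coordinates.
px_to_mask <- function(pixels, pad = 1L) {
  r0 <- min(pixels[, 1]); c0 <- min(pixels[, 2])
  h <- max(pixels[, 1]) - r0 + 1L + 2L * pad
  w <- max(pixels[, 2]) - c0 + 1L + 2L * pad
  m <- matrix(FALSE, h, w)
  m[cbind(pixels[, 1] - r0 + 1L + pad, pixels[, 2] - c0 + 1L + pad)] <- TRUE
  list(mask = m, off = c(r0 - pad, c0 - pad))
}

# Logical matrix marking pixels of `m` with at least one FALSE 4-neighbour
# (image border counts as outside).
boundary_mask <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(FALSE, m[-h, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -w, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & dn & lf & rt)
}

# Boundary pixels of a pixel set, as 0-based (row, col) coordinates.
boundary_pixels <- function(pixels) {
  pm <- px_to_mask(pixels)
  b <- which(boundary_mask(pm$mask), arr.ind = TRUE)
  cbind(b[, 1] - 1L + pm$off[1], b[, 2] - 1L + pm$off[2])
}

# Chain-code perimeter estimate from the 8-connected outer contour, using
# the classical calibrated step weights (0.948 per axis step, 1.340 per
# diagonal step) that remove the systematic overestimation of raw chain
# length on smooth boundaries.
perimeter_crack <- function(pixels) {
  pm <- px_to_mask(pixels)
  oc <- EBImage::ocontour(EBImage::bwlabel(pm$mask * 1L))
  if (length(oc) == 0L) return(0)
  per <- 0
  for (ct in oc) {
    n <- nrow(ct)
    if (n < 2L) next
    st <- abs(ct - ct[c(2:n, 1L), , drop = FALSE])
    diag_step <- st[, 1] > 0 & st[, 2] > 0
    per <- per + 0.948 * sum(!diag_step) + 1.340 * sum(diag_step)
  }
  per
}

# Shoelace polygon area for (x, y) vertices in order.
shoelace <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

# The four corner points of every pixel in the set, as (x, y) = (col, row).
pixel_corners <- function(pixels) {
  r <- pixels[, 1]; c <- pixels[, 2]
  cbind(x = c(c - 0.5, c - 0.5, c + 0.5, c + 0.5),
        y = c(r - 0.5, r + 0.5, r - 0.5, r + 0.5))
}

# Convex-image area of a pixel set: the number of grid pixels whose
# centres lie inside (or on) the convex hull of the set's pixel centres.
# For a convex rasterised shape this equals the pixel count exactly, and
# it is always >= |pixels| since every member's centre is in the hull.
hull_area_px <- function(pixels) {
  if (nrow(pixels) < 3L) return(nrow(pixels))
  pts <- cbind(x = pixels[, 2], y = pixels[, 1])
  h <- chull(pts)
  vx <- pts[h, 1]; vy <- pts[h, 2]
  if (length(h) < 3L) return(nrow(pixels))
  # ensure counter-clockwise orientation
  if (sum(vx * vy[c(2:length(vy), 1)] - vx[c(2:length(vx), 1)] * vy) < 0) {
    vx <- rev(vx); vy <- rev(vy)
  }
  r0 <- min(pixels[, 1]); r1 <- max(pixels[, 1])
  c0 <- min(pixels[, 2]); c1 <- max(pixels[, 2])
  gx <- rep(c0:c1, times = r1 - r0 + 1L)
  gy <- rep(r0:r1, each = c1 - c0 + 1L)
  inside <- rep(TRUE, length(gx))
  n <- length(vx)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    inside <- inside &
      ((vx[j] - vx[i]) * (gy - vy[i]) - (vy[j] - vy[i]) * (gx - vx[i]) >=
         -1e-9)
  }
  sum(inside)
}

# Minimum enclosing circle over a point cloud: minimise the maximum
# distance to a centre (a convex problem) by Nelder-Mead from the hull
# centroid. Returns list(center = c(x, y), radius).
min_enclosing_circle_pts <- function(pts) {
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  f <- function(cc) max(sqrt((hp[, 1] - cc[1])^2 + (hp[, 2] - cc[2])^2))
  c0 <- colMeans(hp)
  fit <- optim(c0, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(center = unname(fit$par), radius = fit$value)
}

# Minimum enclosing circle of a pixel set (over pixel corners).
min_enclosing_circle <- function(pixels) {
  if (nrow(pixels) == 1L)
    return(list(center = c(pixels[1, 2], pixels[1, 1]), radius = sqrt(2) / 2))
  min_enclosing_circle_pts(unique(pixel_corners(pixels)))
}

# Principal axis direction (unit vector, (x, y)) of a pixel set via the
# leading eigenvector of the coordinate covariance; (1, 0) for degenerate
# sets.
principal_axis <- function(pixels) {
  if (nrow(pixels) < 2L) return(c(1, 0))
  xy <- cbind(pixels[, 2], pixels[, 1])
  cv <- cov(xy)
  if (!all(is.finite(cv)) || sum(abs(cv)) < 1e-12) return(c(1, 0))
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}
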