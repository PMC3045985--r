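# Affine registration of the infrared label map onto the H&E image.
#
# Both modalities are reduced to binary tissue masks; the only reliable
# shared features are the macroscopic sample outline and the lumens, so the
# objective is simply the summed absolute difference (symmetric-difference
# pixel count) of the two masks. Because of the binarization no intensity
# transformation is needed. Parameters are translation (tx, ty), rotation
# theta and isotropic scale s, with rotation/scale taken about the target
# mask centroid; the fit uses Nelder-Mead downhill simplex with multiple
# rotation starts.

#' Affine transform parameters
#'
#' @param tx,ty translation in pixels along columns (x) and rows (y).
#' @param theta rotation in radians, normalised into (-pi, pi].
#' @param s isotropic scale factor, must be positive.
#' @return object of class \code{affine_params}.
#' @export
affine_params <- function(tx = 0, ty = 0, theta = 0, s = 1) {
  if (!is.finite(s) || s <= 0) stop("affine_params: scale s must be positive")
  theta <- ((theta + pi) %% (2 * pi)) - pi
  if (theta == -pi) theta <- pi
  structure(list(tx = tx, ty = ty, theta = theta, s = s),
            class = "affine_params")
}

# Centroid of TRUE pixels in (x = col0, y = row0); image centre if empty.
mask_centroid_xy <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(c(x = (ncol(mask) - 1) / 2, y = (nrow(mask) - 1) / 2))
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

#' Apply an affine transform to a binary mask
#'
#' The output pixel at (row, col) is sampled from the inverse-mapped source
#' coordinate with nearest-neighbour interpolation; coordinates mapping
#' outside the source are FALSE. Rotation and scaling act about the source
#' mask's centroid, followed by translation (tx, ty).
#'
#' @param mask \code{\link{binary_mask}} (or logical matrix) to transform.
#' @param params \code{\link{affine_params}}.
#' @param out_shape integer (H, W) of the output grid; defaults to the
#'   input shape.
#' @return a \code{\link{binary_mask}} of shape \code{out_shape}.
#' @export
apply_affine <- function(mask, params, out_shape = NULL) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (is.null(out_shape)) out_shape <- dim(m)
  if (any(out_shape < 1)) stop("apply_affine: out_shape must be >= 1 x 1")
  if (params$s <= 0) stop("apply_affine: scale must be positive")
  H <- out_shape[1]; W <- out_shape[2]
  ctr <- mask_centroid_xy(m)
  co <- cos(params$theta); si <- sin(params$theta)
  # output grid, 0-based centres
  xo <- matrix(rep(0:(W - 1), each = H), H, W)
  yo <- matrix(rep(0:(H - 1), times = W), H, W)
  dx <- xo - ctr[["x"]] - params$tx
  dy <- yo - ctr[["y"]] - params$ty
  xs <- ( co * dx + si * dy) / params$s + ctr[["x"]]
  ys <- (-si * dx + co * dy) / params$s + ctr[["y"]]
  ri <- as.integer(round(ys)) + 1L
  ci <- as.integer(round(xs)) + 1L
  ok <- ri >= 1L & ri <= nrow(m) & ci >= 1L & ci <= ncol(m)
  out <- matrix(FALSE, H, W)
  out[ok] <- m[cbind(ri[ok], ci[ok])]
  binary_mask(out)
}

#' Transform a label image onto another grid
#'
#' Nearest-neighbour inverse mapping of integer labels under the same
#' transform model as \code{\link{apply_affine}}; out-of-bounds pixels get
#' the background code. The transform's centroid pivot is taken from the
#' non-background footprint of the label raster.
#'
#' @param labels integer matrix of label codes.
#' @param params \code{\link{affine_params}}.
#' @param out_shape integer (H, W).
#' @return integer matrix of shape \code{out_shape}.
#' @export
apply_affine_labels <- function(labels, params, out_shape = NULL) {
  if (is.null(out_shape)) out_shape <- dim(labels)
  res <- matrix(IR_LABELS[["background"]], out_shape[1], out_shape[2])
  fg <- labels != IR_LABELS[["background"]]
  for (code in setdiff(unname(IR_LABELS), IR_LABELS[["background"]])) {
    if (!any(labels == code)) next
    # share the pivot of the whole footprint so codes move together
    m <- labels == code
    ctr <- mask_centroid_xy(fg)
    tmp <- apply_affine_with_pivot(m, params, out_shape, ctr)
    res[tmp] <- code
  }
  res
}

# apply_affine with an externally fixed pivot (internal).
apply_affine_with_pivot <- function(m, params, out_shape, ctr) {
  H <- out_shape[1]; W <- out_shape[2]
  co <- cos(params$theta); si <- sin(params$theta)
  xo <- matrix(rep(0:(W - 1), each = H), H, W)
  yo <- matrix(rep(0:(H - 1), times = W), H, W)
  dx <- xo - ctr[["x"]] - params$tx
  dy <- yo - ctr[["y"]] - params$ty
  xs <- ( co * dx + si * dy) / params$s + ctr[["x"]]
  ys <- (-si * dx + co * dy) / params$s + ctr[["y"]]
  ri <- as.integer(round(ys)) + 1L
  ci <- as.integer(round(xs)) + 1L
  ok <- ri >= 1L & ri <= nrow(m) & ci >= 1L & ci <= ncol(m)
  out <- matrix(FALSE, H, W)
  out[ok] <- m[cbind(ri[ok], ci[ok])]
  out
}

#' Registration objective: absolute mask difference
#'
#' @param reference \code{\link{binary_mask}} defining the fixed grid.
#' @param target \code{\link{binary_mask}} to be transformed.
#' @param params \code{\link{affine_params}}.
#' @return nonnegative count of pixels where the reference and the
#'   transformed target disagree.
#' @export
registration_objective <- function(reference, target, params) {
  ref <- if (inherits(reference, "binary_mask")) reference$mask else reference
  tr <- apply_affine(target, params, dim(ref))$mask
  sum(xor(ref, tr))
}

#' Register a target mask onto a reference mask
#'
#' Minimises the symmetric-difference objective by Nelder-Mead downhill
#' simplex. Initialisation: scale from the square root of the true-area
#' ratio, translation aligning centroids, rotation zero; five restarts
#' perturb the initial rotation by 0, +/-0.1 and +/-0.2 rad to escape local
#' minima, the best final objective winning (ties broken towards the
#' smallest absolute rotation).
#'
#' @param reference,target \code{\link{binary_mask}} objects; both must
#'   contain at least one TRUE pixel.
#' @param init optional \code{\link{affine_params}} overriding the
#'   automatic initialisation.
#' @param theta_starts rotation perturbations (radians) for the restarts.
#' @param maxit simplex iteration cap per restart.
#' @param abstol absolute objective tolerance for simplex termination
#'   (pixels).
#' @return object of class \code{registration_result}: \code{params},
#'   \code{objective}, \code{n_evaluations}.
#' @export
register <- function(reference, target, init = NULL,
                     theta_starts = c(0, -0.1, 0.1, -0.2, 0.2),
                     maxit = 500, abstol = 0.5) {
  ref <- if (inherits(reference, "binary_mask")) reference$mask else reference
  tgt <- if (inherits(target, "binary_mask")) target$mask else target
  if (!any(ref) || !any(tgt))
    stop("register: both masks must contain at least one TRUE pixel")
  a_ref <- sum(ref); a_tgt <- sum(tgt)
  c_ref <- mask_centroid_xy(ref); c_tgt <- mask_centroid_xy(tgt)
  if (is.null(init)) {
    init <- affine_params(tx = c_ref[["x"]] - c_tgt[["x"]],
                          ty = c_ref[["y"]] - c_tgt[["y"]],
                          theta = 0, s = sqrt(a_ref / a_tgt))
  }
  n_eval <- 0L
  fn <- function(p) {
    n_eval <<- n_eval + 1L
    if (p[4] <= 0.05) return(length(ref))  # guard: scale collapse
    registration_objective(ref, tgt, affine_params(p[1], p[2], p[3], p[4]))
  }
  best <- NULL
  for (dth in theta_starts) {
    p0 <- c(init$tx, init$ty, init$theta + dth, init$s)
    fit <- optim(p0, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, abstol = abstol,
                                reltol = 1e-8,
                                parscale = c(2, 2, 0.05, 0.02 * init$s)))
    cand <- list(par = fit$par, value = fit$value)
    if (is.null(best) || cand$value < best$value ||
        (cand$value == best$value && abs(cand$par[3]) < abs(best$par[3])))
      best <- cand
  }
  structure(list(params = affine_params(best$par[1], best$par[2],
                                        best$par[3], best$par[4]),
                 objective = best$value,
                 n_evaluations = n_eval),
            class = "registration_result")
}

# Block-average downsample of a logical mask by integer factor f
# (TRUE where >= half the block is TRUE).
downsample_mask <- function(mask, f) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  f <- as.integer(f)
  H <- (nrow(m) %/% f) * f; W <- (ncol(m) %/% f) * f
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  a <- array(m, c(f, H %/% f, f, W %/% f))
  binary_mask(apply(a, c(2, 4), mean) >= 0.5)
}

#' Rescale affine parameters from a coarse output grid to a fine one
#'
#' If registration was run against a reference downsampled by integer
#' factor \code{f} (coarse pixel \code{i} covering fine pixels with centre
#' \code{f*i + (f-1)/2}), this returns the parameters that reproduce the
#' same transform of the unresampled target directly onto the fine grid.
#'
#' @param params coarse-grid \code{\link{affine_params}}.
#' @param target the target mask the registration used (for its centroid).
#' @param f integer downsampling factor of the reference grid.
#' @return fine-grid \code{\link{affine_params}}.
#' @export
scale_affine_params <- function(params, target, f) {
  m <- if (inherits(target, "binary_mask")) target$mask else target
  ctr <- mask_centroid_xy(m)
  off <- (f - 1) / 2
  affine_params(tx = f * params$tx + (f - 1) * ctr[["x"]] + off,
                ty = f * params$ty + (f - 1) * ctr[["y"]] + off,
                theta = params$theta, s = f * params$s)
}

#' Register a sample pair's label map onto its H&E grid
#'
#' Bridges the resolution gap by registering the label-map tissue mask
#' against the H&E tissue mask downsampled to a comparable grid (integer
#' factor near the physical pixel-size ratio), then rescaling the fitted
#' parameters to the full H&E grid.
#'
#' @param pair \code{\link{sample_pair}}.
#' @param white_threshold channel threshold for \code{\link{binarize_he}}.
#' @param coarse_factor integer downsampling factor for the H&E mask;
#'   \code{NULL} picks \code{floor(ir_um / he_um)}.
#' @param ... passed to \code{\link{register}}.
#' @return \code{registration_result} whose \code{params} act on the full
#'   H&E grid; the \code{objective} is reported on the coarse grid, with
#'   \code{coarse_factor} recorded.
#' @export
register_pair <- function(pair, white_threshold = 200, coarse_factor = NULL,
                          ...) {
  stopifnot(inherits(pair, "sample_pair"))
  if (is.null(coarse_factor))
    coarse_factor <- max(1L, floor(pair$ir$pixel_size_um /
                                     pair$he$pixel_size_um))
  he_mask <- binarize_he(pair$he, white_threshold)
  ref <- downsample_mask(he_mask, coarse_factor)
  tgt <- binarize_ir(pair$ir)
  res <- register(ref, tgt, ...)
  fine <- scale_affine_params(res$params, tgt, coarse_factor)
  structure(list(params = fine, objective = res$objective,
                 n_evaluations = res$n_evaluations,
                 coarse_factor = coarse_factor),
            class = "registration_result")
}
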