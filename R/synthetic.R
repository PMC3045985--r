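# Synthetic paired H&E / cell-type-map generator with exact ground truth.
#
# Emulates the morphology the classifier exploits: benign tissue has few,
# large, irregular lumens ringed by a thin ordered layer of epithelium
# with sparse nuclei; cancerous tissue has many small round lumens, thick
# epithelium with dense (and slightly larger) nuclei, plus infiltrative
# epithelial foci without lumens. The cell-type map is rendered at the
# coarser infrared pixel grid and given a small random affine jitter so
# registration is genuinely exercised.

#' Parameters of the synthetic tissue generator
#'
#' Defaults depend on \code{class_profile}; the two presets encode the
#' canonical benign-vs-carcinoma contrasts (lumen size and shape, nuclear
#' density and size, epithelial ring thickness, infiltrative foci).
#'
#' @param class_profile "benign" or "cancer".
#' @param img_size H&E canvas edge (px).
#' @param n_glands number of glands.
#' @param lumen_radius_mean,lumen_radius_sd,lumen_min_radius lumen radius
#'   distribution (px).
#' @param lumen_shape_distortion amplitude of the radial boundary
#'   perturbation (0 = perfect disc).
#' @param epithelial_ring_width epithelium thickness around each lumen (px).
#' @param nuclear_density nuclei per 1000 px^2 of epithelium.
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus size (px).
#' @param n_foci epithelial foci without a lumen (infiltration).
#' @param stain_shift additive RGB offset simulating staining variation.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   units); 8 is the moderate-noise preset.
#' @param ir_jitter apply a small random affine jitter to the cell-type
#'   map (so registration has something to recover).
#' @param seed RNG seed; rendering is deterministic given the seed.
#' @return named list of class \code{tissue_params}.
#' @export
tissue_params <- function(class_profile = c("benign", "cancer"),
                          img_size = 256,
                          n_glands = NULL,
                          lumen_radius_mean = NULL, lumen_radius_sd = NULL,
                          lumen_min_radius = NULL,
                          lumen_shape_distortion = NULL,
                          epithelial_ring_width = NULL,
                          nuclear_density = NULL,
                          nucleus_radius_mean = NULL,
                          nucleus_radius_sd = 0.4,
                          n_foci = NULL,
                          stain_shift = c(0, 0, 0), noise_sd = 8,
                          ir_jitter = TRUE, seed = 1) {
  class_profile <- match.arg(class_profile)
  d <- if (class_profile == "benign") {
    list(n_glands = 5, lumen_radius_mean = 20, lumen_radius_sd = 4,
         lumen_min_radius = 12, lumen_shape_distortion = 0.25,
         epithelial_ring_width = 10, nuclear_density = 6,
         nucleus_radius_mean = 3.4, n_foci = 0)
  } else {
    list(n_glands = 12, lumen_radius_mean = 8, lumen_radius_sd = 1.5,
         lumen_min_radius = 5, lumen_shape_distortion = 0.08,
         epithelial_ring_width = 14, nuclear_density = 10,
         nucleus_radius_mean = 4.0, n_foci = 3)
  }
  pick <- function(x, dflt) if (is.null(x)) dflt else x
  p <- list(class_profile = class_profile, img_size = img_size,
            n_glands = pick(n_glands, d$n_glands),
            lumen_radius_mean = pick(lumen_radius_mean, d$lumen_radius_mean),
            lumen_radius_sd = pick(lumen_radius_sd, d$lumen_radius_sd),
            lumen_min_radius = pick(lumen_min_radius, d$lumen_min_radius),
            lumen_shape_distortion = pick(lumen_shape_distortion,
                                          d$lumen_shape_distortion),
            epithelial_ring_width = pick(epithelial_ring_width,
                                         d$epithelial_ring_width),
            nuclear_density = pick(nuclear_density, d$nuclear_density),
            nucleus_radius_mean = pick(nucleus_radius_mean,
                                       d$nucleus_radius_mean),
            nucleus_radius_sd = nucleus_radius_sd,
            n_foci = pick(n_foci, d$n_foci),
            stain_shift = stain_shift, noise_sd = noise_sd,
            ir_jitter = ir_jitter, seed = seed)
  stopifnot(p$img_size >= 64, p$n_glands >= 1, p$lumen_radius_mean > 0,
            p$epithelial_ring_width > 0, p$nucleus_radius_mean > 0)
  structure(p, class = "tissue_params")
}

# Stain palette (R, G, B in 0..255).
SYNTH_COLORS <- list(glass = c(255, 255, 255), lumen = c(250, 250, 250),
                     stroma = c(235, 195, 205), cytoplasm = c(225, 160, 190),
                     nucleus = c(70, 70, 160))

# Distorted radial boundary r(phi) = r0 * (1 + d * z(phi)) with a few
# random low-order harmonics, clamped at 0.4 * r0.
radial_fn <- function(r0, distortion) {
  ks <- 2:4
  amp <- runif(3); amp <- amp / sum(amp)
  ph <- runif(3, 0, 2 * pi)
  function(phi) {
    z <- amp[1] * cos(ks[1] * phi + ph[1]) +
      amp[2] * cos(ks[2] * phi + ph[2]) +
      amp[3] * cos(ks[3] * phi + ph[3])
    pmax(r0 * (1 + distortion * z), 0.4 * r0)
  }
}

#' Render one synthetic sample with ground truth
#'
#' @param p \code{\link{tissue_params}}.
#' @return list with \code{pair} (a \code{\link{sample_pair}}) and
#'   \code{truth}: \code{lumens}, \code{nuclei} (lists of segmentation
#'   objects), \code{epithelium_mask}, \code{tissue_mask},
#'   \code{class_label}, and \code{ir_jitter_params} when jitter was
#'   applied.
#' @export
render_sample <- function(p = tissue_params()) {
  stopifnot(inherits(p, "tissue_params"))
  with_local_seed(p$seed, render_sample_impl(p))
}

render_sample_impl <- function(p) {
  S <- p$img_size
  ctr <- (S - 1) / 2
  t_rad <- 0.44 * S
  xo <- matrix(rep(0:(S - 1), each = S), S, S)   # col coordinate
  yo <- matrix(rep(0:(S - 1), times = S), S, S)  # row coordinate
  tissue <- (xo - ctr)^2 + (yo - ctr)^2 <= t_rad^2
  R <- matrix(SYNTH_COLORS$glass[1], S, S)
  G <- matrix(SYNTH_COLORS$glass[2], S, S)
  B <- matrix(SYNTH_COLORS$glass[3], S, S)
  paint <- function(mask, col) {
    R[mask] <<- col[1]; G[mask] <<- col[2]; B[mask] <<- col[3]
  }
  paint(tissue, SYNTH_COLORS$stroma)

  epi <- matrix(FALSE, S, S)
  lum_all <- matrix(FALSE, S, S)
  lumen_list <- list()
  gland_centers <- matrix(numeric(0), 0, 2)
  gland_radii <- numeric(0)

  place <- function(gr) {
    # rejection-sample a gland centre keeping glands inside the tissue and
    # apart from each other
    for (a in 1:100) {
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * (t_rad - gr - 6)
      cc <- c(ctr + rad * sin(ang), ctr + rad * cos(ang))  # (row, col)
      if (nrow(gland_centers) == 0L) return(cc)
      dd <- sqrt((gland_centers[, 1] - cc[1])^2 +
                   (gland_centers[, 2] - cc[2])^2)
      if (all(dd > gland_radii + gr + 4)) return(cc)
    }
    NULL
  }

  n_fail <- 0L
  for (g in seq_len(p$n_glands)) {
    r0 <- max(p$lumen_min_radius,
              rnorm(1, p$lumen_radius_mean, p$lumen_radius_sd))
    gr <- r0 * (1 + p$lumen_shape_distortion) + p$epithelial_ring_width + 2
    cc <- place(gr)
    if (is.null(cc)) { n_fail <- n_fail + 1L; next }
    gland_centers <- rbind(gland_centers, cc)
    gland_radii <- c(gland_radii, gr)
    rf <- radial_fn(r0, p$lumen_shape_distortion)
    phi <- atan2(yo - cc[1], xo - cc[2])
    dd <- sqrt((yo - cc[1])^2 + (xo - cc[2])^2)
    rb <- rf(phi)
    lum <- dd < rb
    ring <- dd >= rb & dd < rb + p$epithelial_ring_width
    paint(lum, SYNTH_COLORS$lumen)
    paint(ring, SYNTH_COLORS$cytoplasm)
    epi <- epi | ring
    lum_all <- lum_all | lum
    idx <- which(lum, arr.ind = TRUE)
    lumen_list[[length(lumen_list) + 1L]] <-
      lumen_object(cbind(idx[, 1] - 1L, idx[, 2] - 1L), complete = TRUE)
  }
  if (length(lumen_list) == 0L)
    stop("render_sample: could not place any gland (packing limit)")

  # infiltrative epithelial foci (no lumen)
  for (f in seq_len(p$n_foci)) {
    fr <- runif(1, 8, 12)
    cc <- place(fr)
    if (is.null(cc)) next
    gland_centers <- rbind(gland_centers, cc)
    gland_radii <- c(gland_radii, fr)
    foc <- (yo - cc[1])^2 + (xo - cc[2])^2 <= fr^2
    paint(foc, SYNTH_COLORS$cytoplasm)
    epi <- epi | foc
  }

  # nuclei inside the epithelium
  nuc_list <- list()
  nuc_centers <- matrix(numeric(0), 0, 2)
  epi_idx <- which(epi, arr.ind = TRUE)
  n_nuc <- round(p$nuclear_density * nrow(epi_idx) / 1000)
  min_sep <- 3.0 * p$nucleus_radius_mean
  attempts <- 0L
  while (length(nuc_list) < n_nuc && attempts < n_nuc * 60L) {
    attempts <- attempts + 1L
    k <- sample(nrow(epi_idx), 1L)
    cc <- c(epi_idx[k, 1] - 1L, epi_idx[k, 2] - 1L)
    if (nrow(nuc_centers) &&
        min(sqrt((nuc_centers[, 1] - cc[1])^2 +
                   (nuc_centers[, 2] - cc[2])^2)) < min_sep) next
    rad <- max(2.2, rnorm(1, p$nucleus_radius_mean, p$nucleus_radius_sd))
    a <- rad * 1.25; b <- rad * 0.8
    th <- runif(1, 0, pi)
    dxr <- xo - cc[2]; dyr <- yo - cc[1]
    u <- dxr * cos(th) + dyr * sin(th)
    v <- -dxr * sin(th) + dyr * cos(th)
    ell <- (u / a)^2 + (v / b)^2 <= 1
    ell <- ell & tissue
    if (any(ell & lum_all)) next   # keep lumens and nuclei disjoint
    if (sum(ell) < 10) next
    paint(ell, SYNTH_COLORS$nucleus)
    epi <- epi | ell      # nuclei belong to epithelial cells
    idx <- which(ell, arr.ind = TRUE)
    nuc_list[[length(nuc_list) + 1L]] <-
      nucleus_object(cbind(idx[, 1] - 1L, idx[, 2] - 1L))
    nuc_centers <- rbind(nuc_centers, cc)
  }

  # stain shift and noise
  R <- R + p$stain_shift[1]; G <- G + p$stain_shift[2]
  B <- B + p$stain_shift[3]
  if (p$noise_sd > 0) {
    R <- R + rnorm(S * S, 0, p$noise_sd)
    G <- G + rnorm(S * S, 0, p$noise_sd)
    B <- B + rnorm(S * S, 0, p$noise_sd)
  }
  he_arr <- array(0, c(S, S, 3))
  he_arr[, , 1] <- pmin(pmax(round(R), 0), 255)
  he_arr[, , 2] <- pmin(pmax(round(G), 0), 255)
  he_arr[, , 3] <- pmin(pmax(round(B), 0), 255)
  he <- rgb_image(he_arr)

  # cell-type map on the coarse infrared grid
  ratio <- 6.25 / 0.9636
  ir_n <- floor(S / ratio)
  ir_lab <- matrix(IR_LABELS[["background"]], ir_n, ir_n)
  for (i in seq_len(ir_n)) {
    rr <- (floor((i - 1) * ratio) + 1L):min(S, floor(i * ratio))
    for (j in seq_len(ir_n)) {
      cc2 <- (floor((j - 1) * ratio) + 1L):min(S, floor(j * ratio))
      blk_e <- mean(epi[rr, cc2])
      blk_l <- mean(lum_all[rr, cc2])
      blk_t <- mean(tissue[rr, cc2])
      # empty lumen space carries no tissue signal: background
      ir_lab[i, j] <- if (blk_e >= 0.25) IR_LABELS[["epithelium"]]
                      else if (blk_l >= 0.5) IR_LABELS[["background"]]
                      else if (blk_t >= 0.5) IR_LABELS[["stroma"]]
                      else IR_LABELS[["background"]]
    }
  }
  jit <- NULL
  if (isTRUE(p$ir_jitter)) {
    jit <- affine_params(tx = runif(1, -1.5, 1.5), ty = runif(1, -1.5, 1.5),
                         theta = runif(1, -0.03, 0.03),
                         s = runif(1, 0.98, 1.02))
    ir_lab <- apply_affine_labels(ir_lab, jit)
  }
  pair <- sample_pair(he, label_image(ir_lab),
                      sample_id = sprintf("%s_seed%d", p$class_profile,
                                          p$seed),
                      class_label = if (p$class_profile == "cancer") 1 else 0)
  list(pair = pair,
       truth = list(lumens = lumen_list, nuclei = nuc_list,
                    epithelium_mask = binary_mask(epi),
                    tissue_mask = binary_mask(tissue),
                    class_label = pair$class_label,
                    ir_jitter_params = jit))
}

#' Render a cohort to disk
#'
#' Writes one H&E PNG and one label-map PNG per sample plus a manifest CSV
#' (\code{sample_id}, \code{he_path}, \code{ir_path}, \code{label}).
#'
#' @param n_benign,n_cancer samples per class.
#' @param out_dir output directory (created if needed).
#' @param seed cohort seed; per-sample seeds derive from it.
#' @param base_benign,base_cancer parameter presets to use per class.
#' @return the manifest data.frame, invisibly; the manifest is written to
#'   \code{out_dir/manifest.csv}.
#' @export
render_cohort <- function(n_benign, n_cancer, out_dir, seed = 1,
                          base_benign = tissue_params("benign"),
                          base_cancer = tissue_params("cancer")) {
  stopifnot(n_benign >= 1, n_cancer >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  k <- 0L
  for (cls in c("benign", "cancer")) {
    n <- if (cls == "benign") n_benign else n_cancer
    base <- if (cls == "benign") base_benign else base_cancer
    for (i in seq_len(n)) {
      k <- k + 1L
      p <- base
      p$seed <- seed * 1000L + k
      smp <- render_sample(p)
      id <- sprintf("%s_%03d", cls, i)
      he_path <- file.path(out_dir, paste0(id, "_he.png"))
      ir_path <- file.path(out_dir, paste0(id, "_ir.png"))
      png::writePNG(smp$pair$he$pixels / 255, he_path)
      png::writePNG(smp$pair$ir$labels / 255, ir_path)
      rows[[k]] <- data.frame(sample_id = id,
                              he_path = basename(he_path),
                              ir_path = basename(ir_path),
                              label = smp$truth$class_label)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Simulate a feature table with planted class signal
#'
#' Gaussian features; informative columns are shifted between classes by
#' the given effect sizes; optional redundant columns correlate with a
#' source column.
#'
#' @param n samples (balanced classes).
#' @param M features, named \code{f1..fM}.
#' @param informative_ids column indices carrying signal.
#' @param effect_sizes per-informative-column mean shift (in SD units).
#' @param redundant optional data.frame with columns \code{src},
#'   \code{dst}, \code{r}: column \code{dst} is rebuilt as a copy of
#'   \code{src} with correlation \code{r}.
#' @param seed RNG seed.
#' @return list(X = matrix, y = 0/1 labels).
#' @export
simulate_feature_table <- function(n, M, informative_ids = integer(0),
                                   effect_sizes = numeric(0),
                                   redundant = NULL, seed = 1) {
  stopifnot(length(informative_ids) == length(effect_sizes),
            M >= length(informative_ids))
  with_local_seed(seed, {
    y <- sample(rep(0:1, length.out = n))
    X <- matrix(rnorm(n * M), n, M)
    for (k in seq_along(informative_ids))
      X[, informative_ids[k]] <- X[, informative_ids[k]] +
        effect_sizes[k] * y
    if (!is.null(redundant))
      for (k in seq_len(nrow(redundant))) {
        r <- redundant$r[k]
        X[, redundant$dst[k]] <- r * X[, redundant$src[k]] +
          sqrt(1 - r^2) * rnorm(n)
      }
    colnames(X) <- paste0("f", seq_len(M))
    list(X = X, y = y)
  })
}
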