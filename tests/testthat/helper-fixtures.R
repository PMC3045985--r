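# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures on disk.

# Pixel sets ---------------------------------------------------------------

disc_pixels <- function(R, pad = 3L) {
  S <- 2L * R + 2L * pad
  ct <- (S - 1) / 2
  which(outer(0:(S - 1), 0:(S - 1),
              function(r, c) (r - ct)^2 + (c - ct)^2 <= R^2),
        arr.ind = TRUE) - 1L
}

square_pixels <- function(a) {
  as.matrix(expand.grid(0:(a - 1), 0:(a - 1)))
}

ellipse_pixels <- function(a, b, theta = 0) {
  S <- 2L * max(a, b) + 11L
  ct <- (S - 1) / 2
  co <- cos(theta); si <- sin(theta)
  which(outer(0:(S - 1), 0:(S - 1), function(r, c) {
    u <- (c - ct) * co + (r - ct) * si
    v <- -(c - ct) * si + (r - ct) * co
    (u / a)^2 + (v / b)^2 <= 1
  }), arr.ind = TRUE) - 1L
}

# Solid-colour H&E canvases ------------------------------------------------

HE_PINK <- c(230, 150, 190)     # cytoplasm / stroma-like
HE_WHITE <- c(250, 250, 250)    # lumen / glass
HE_BLUE <- c(60, 60, 150)       # nucleus

he_canvas <- function(H, W, col = HE_PINK) {
  a <- array(0, c(H, W, 3))
  for (k in 1:3) a[, , k] <- col[k]
  a
}

he_fill <- function(arr, mask, col) {
  for (k in 1:3) {
    ch <- arr[, , k]; ch[mask] <- col[k]; arr[, , k] <- ch
  }
  arr
}

circle_mask <- function(H, W, ctr_rc, R) {
  outer(0:(H - 1), 0:(W - 1),
        function(r, c) (r - ctr_rc[1])^2 + (c - ctr_rc[2])^2 <= R^2)
}

ring_mask <- function(H, W, ctr_rc, R1, R2) {
  circle_mask(H, W, ctr_rc, R2) & !circle_mask(H, W, ctr_rc, R1)
}

# A tissue-like blob mask for registration tests: disc with lobes and
# holes, deterministic given the seed.
blob_mask <- function(seed, S = 160) {
  set.seed(seed)
  ct <- (S - 1) / 2
  xo <- matrix(rep(0:(S - 1), each = S), S, S)
  yo <- matrix(rep(0:(S - 1), times = S), S, S)
  m <- (xo - ct)^2 + (yo - ct)^2 <= (0.32 * S)^2
  for (k in 1:6) {
    cc <- ct + runif(2, -0.22, 0.22) * S
    r <- runif(1, 0.03 * S, 0.09 * S)
    if (k %% 2 == 1) m <- m & !((xo - cc[1])^2 + (yo - cc[2])^2 <= r^2)
    else m <- m | ((xo - cc[1])^2 + (yo - cc[2])^2 <= (r + 0.03 * S)^2)
  }
  m
}

# Greedy one-to-one centroid matching; returns c(hits, n_truth, n_det).
match_objects <- function(truth, det, tol = 5) {
  tc <- if (length(truth))
    t(vapply(truth, function(x) x$centroid, numeric(2)))
  else matrix(numeric(0), 0, 2)
  dc <- if (length(det))
    t(vapply(det, function(x) x$centroid, numeric(2)))
  else matrix(numeric(0), 0, 2)
  used <- rep(FALSE, nrow(dc)); hits <- 0L
  for (i in seq_len(nrow(tc))) {
    if (nrow(dc) == 0L) break
    d <- sqrt((dc[, 1] - tc[i, 1])^2 + (dc[, 2] - tc[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) { hits <- hits + 1L; used[j] <- TRUE }
  }
  c(hits = hits, n_truth = nrow(tc), n_det = nrow(dc))
}

# A hand-assembled segmentation_result (no image pipeline involved).
manual_seg <- function(H, W, lumens = list(), nuclei = list(),
                       epi = NULL, tissue = NULL) {
  if (is.null(epi)) epi <- matrix(TRUE, H, W)
  if (is.null(tissue)) tissue <- matrix(TRUE, H, W)
  structure(list(lumens = lumens, nuclei = nuclei,
                 epithelium_mask = binary_mask(epi),
                 tissue_mask = binary_mask(tissue),
                 tissue_circle = list(center = c((W - 1) / 2, (H - 1) / 2),
                                      radius = sqrt(2) * max(H, W) / 2),
                 registration = NULL),
            class = "segmentation_result")
}
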