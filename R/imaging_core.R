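# Shared data model and raster I/O.
#
# Coordinate convention used throughout the package: 0-based, row-major
# (row, col) with pixel-center coordinates. All geometry downstream of
# registration lives on the H&E pixel grid.

#' Labels recognised in a cell-type label image
#'
#' Closed vocabulary: 0 = background, 1 = epithelium, 2 = stroma, 3 = other.
#' Any richer upstream histologic model must be collapsed onto these codes
#' before entering the pipeline; only epithelium is consumed downstream.
#' @export
IR_LABELS <- c(background = 0L, epithelium = 1L, stroma = 2L, other = 3L)

#' Construct an RGB H&E image
#'
#' @param pixels numeric H x W x 3 array of channel intensities in
#'   \code{[0, 255]}.
#' @param pixel_size_um physical pixel edge length in micrometres.
#'   The default matches 40x brightfield acquisition.
#' @return an object of class \code{rgb_image} with fields \code{pixels}
#'   and \code{pixel_size_um}.
#' @export
rgb_image <- function(pixels, pixel_size_um = 0.9636) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("rgb_image: `pixels` must be an H x W x 3 array")
  if (any(pixels < 0) || any(pixels > 255))
    stop("rgb_image: channel values must lie in [0, 255]")
  if (pixel_size_um <= 0) stop("rgb_image: pixel_size_um must be positive")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "rgb_image")
}

#' Construct a cell-type label image
#'
#' @param labels integer H x W matrix of codes from \code{\link{IR_LABELS}}.
#' @param pixel_size_um physical pixel edge length in micrometres; the
#'   default matches the infrared imaging grid.
#' @return an object of class \code{label_image}.
#' @export
label_image <- function(labels, pixel_size_um = 6.25) {
  labels <- as.matrix(labels)
  bad <- setdiff(unique(as.vector(labels)), unname(IR_LABELS))
  if (length(bad))
    stop("label_image: unknown label code(s): ", paste(bad, collapse = ", "))
  if (pixel_size_um <= 0) stop("label_image: pixel_size_um must be positive")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_image")
}

#' Construct a binary mask
#'
#' @param mask logical H x W matrix.
#' @return an object of class \code{binary_mask} wrapping the matrix.
#' @export
binary_mask <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask), class = "binary_mask")
}

#' Bundle one sample's two modalities
#'
#' @param he \code{\link{rgb_image}}.
#' @param ir \code{\link{label_image}}.
#' @param sample_id character scalar, unique within a cohort.
#' @param class_label 0 (benign), 1 (cancer) or \code{NA} when unknown.
#' @return an object of class \code{sample_pair}.
#' @export
sample_pair <- function(he, ir, sample_id = "sample", class_label = NA) {
  stopifnot(inherits(he, "rgb_image"), inherits(ir, "label_image"))
  if (!is.na(class_label) && !class_label %in% c(0, 1))
    stop("sample_pair: class_label must be 0, 1 or NA")
  structure(list(he = he, ir = ir, sample_id = as.character(sample_id),
                 class_label = class_label),
            class = "sample_pair")
}

# Read a raster file into a numeric array in [0, 1]. PNG and TIFF only.
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster, no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '", ext, "' for: ", path))
  x
}

#' Read an H&E image from disk
#'
#' @param path PNG or TIFF file storing an 8-bit RGB image.
#' @param pixel_size_um physical pixel size to record.
#' @return an \code{\link{rgb_image}}.
#' @export
read_he_image <- function(path, pixel_size_um = 0.9636) {
  x <- read_raster(path)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) {
    x <- x[, , 1:3, drop = FALSE]
  } else {
    stop("H&E image is not RGB: ", path)
  }
  rgb_image(round(x * 255), pixel_size_um = pixel_size_um)
}

#' Read a cell-type label image from disk
#'
#' Accepts a PNG/TIFF raster whose 8-bit values are the label codes, or a
#' headerless CSV grid of integer codes.
#'
#' @param path PNG, TIFF or CSV file.
#' @param pixel_size_um physical pixel size to record.
#' @return a \code{\link{label_image}}.
#' @export
read_label_image <- function(path, pixel_size_um = 6.25) {
  if (!file.exists(path)) stop("cannot read label image, no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    labels <- as.matrix(read.csv(path, header = FALSE))
    dimnames(labels) <- NULL
  } else {
    x <- read_raster(path)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    labels <- round(x * 255)
  }
  label_image(labels, pixel_size_um = pixel_size_um)
}

#' Read a sample's H&E image and label map as a pair
#'
#' @param he_path path to the H&E raster (PNG/TIFF).
#' @param ir_path path to the label raster (PNG/TIFF/CSV).
#' @param sample_id identifier for the sample.
#' @param class_label 0/1/NA class label.
#' @param he_pixel_um,ir_pixel_um physical pixel sizes.
#' @return a \code{\link{sample_pair}}.
#' @export
read_sample_pair <- function(he_path, ir_path, sample_id = "sample",
                             class_label = NA,
                             he_pixel_um = 0.9636, ir_pixel_um = 6.25) {
  sample_pair(read_he_image(he_path, he_pixel_um),
              read_label_image(ir_path, ir_pixel_um),
              sample_id = sample_id, class_label = class_label)
}

#' Binarize an H&E image into a tissue mask
#'
#' A pixel is "white" (empty glass or lumen) when all three channels exceed
#' the threshold; tissue is everything else. The conjunction over channels
#' matches the definition of lumens as empty white space.
#'
#' @param img an \code{\link{rgb_image}}.
#' @param white_threshold channel intensity above which a channel counts as
#'   white; all three channels must exceed it.
#' @return a \code{\link{binary_mask}}, TRUE where tissue is present.
#' @export
binarize_he <- function(img, white_threshold = 200) {
  stopifnot(inherits(img, "rgb_image"))
  if (white_threshold < 0 || white_threshold > 255)
    stop("binarize_he: white_threshold must lie in [0, 255]")
  p <- img$pixels
  white <- (p[, , 1] > white_threshold) & (p[, , 2] > white_threshold) &
    (p[, , 3] > white_threshold)
  binary_mask(!white)
}

# White mask: complement of the tissue mask under the same threshold rule.
white_mask_he <- function(img, white_threshold = 200) {
  !binarize_he(img, white_threshold)$mask
}

#' Binarize a label image into a tissue-presence mask
#'
#' @param img a \code{\link{label_image}}.
#' @return a \code{\link{binary_mask}}, TRUE wherever the label is not
#'   background.
#' @export
binarize_ir <- function(img) {
  stopifnot(inherits(img, "label_image"))
  binary_mask(img$labels != IR_LABELS[["background"]])
}

#' Read a cohort manifest
#'
#' @param path CSV with columns \code{sample_id}, \code{he_path},
#'   \code{ir_path}, \code{label}; relative paths are resolved against the
#'   manifest's directory.
#' @return data.frame with absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "he_path", "ir_path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  m$he_path <- fix(m$he_path)
  m$ir_path <- fix(m$ir_path)
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  m
}
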