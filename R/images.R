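#' Raster containers for the panicle pipeline
#'
#' The pipeline passes images through four raster stages, each a thin S3
#' wrapper around a base matrix/array so that ordinary subsetting and
#' arithmetic keep working: `rgb_image` (H x W x 3 integer array, channel
#' values 0-255), `gray_image` (H x W integer matrix, 0-255),
#' `binary_mask` (H x W logical matrix, `TRUE` = panicle material) and
#' `labeled_mask` (H x W integer matrix, 0 = background, labels 1..n).
#' All carry a `dpi` attribute (dots per inch; `NA` when unknown) used
#' only for pixel-to-centimetre conversion of length traits.
#'
#' Raster convention: row-major reading order, origin at the top-left,
#' `x[i, j]` is the pixel in image row `i` (from the top) and column `j`.
#'
#' @param pixels For `rgb_image` an H x W x 3 numeric array with values in
#'   0-255; for `gray_image` an H x W numeric matrix in 0-255; for
#'   `binary_mask` an H x W logical (or 0/1 numeric) matrix; for
#'   `labeled_mask` an H x W matrix of non-negative integer labels.
#' @param dpi Scan resolution in dots per inch, or `NA` if unknown.
#' @return An object of the corresponding class.
#' @name rasters
NULL

#' @rdname rasters
#' @export
rgb_image <- function(pixels, dpi = NA_real_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("not an RGB image: expected an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(pixels, dpi = as.numeric(dpi), class = "rgb_image")
}

#' @rdname rasters
#' @export
gray_image <- function(pixels, dpi = NA_real_) {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("gray values must lie in [0, 255]", call. = FALSE)
  structure(pixels, dpi = as.numeric(dpi), class = "gray_image")
}

#' @rdname rasters
#' @export
binary_mask <- function(pixels, dpi = NA_real_) {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("binary mask values must be logical or 0/1", call. = FALSE)
    pixels <- pixels > 0
  }
  structure(pixels, dpi = as.numeric(dpi), class = "binary_mask")
}

#' @rdname rasters
#' @export
labeled_mask <- function(pixels, dpi = NA_real_) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L)
    stop("labels must be non-negative integers", call. = FALSE)
  n <- if (any(pixels > 0L)) max(pixels) else 0L
  if (n > 0L && !all(seq_len(n) %in% unique(pixels[pixels > 0L])))
    stop("labels must be 1..n_regions with no gaps", call. = FALSE)
  structure(pixels, dpi = as.numeric(dpi), n_regions = as.integer(n),
            class = "labeled_mask")
}

#' @rdname rasters
#' @param x A raster object.
#' @export
img_dpi <- function(x) {
  d <- attr(x, "dpi")
  if (is.null(d)) NA_real_ else d
}

#' @rdname rasters
#' @export
n_regions <- function(x) {
  stopifnot(inherits(x, "labeled_mask"))
  attr(x, "n_regions")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, dpi %s>\n", nrow(x), ncol(x),
              format(img_dpi(x))))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, dpi %s>\n", nrow(x), ncol(x),
              format(img_dpi(x))))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask %d x %d, %d regions>\n",
              nrow(x), ncol(x), n_regions(x)))
  invisible(x)
}

# strip class/attrs down to a plain base object for arithmetic
as_plain <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Read a panicle scan from disk
#'
#' Reads a PNG, JPEG or TIFF scan into an [rgb_image]. An alpha channel is
#' dropped; single-channel files are kept as a degenerate 1-channel array
#' (downstream [to_gray()] will refuse them). The resolution is taken from
#' file metadata when the format records it (PNG, TIFF), otherwise from
#' the `dpi` argument.
#'
#' @param path Path to an image file.
#' @param dpi Fallback resolution in dots per inch when the file carries
#'   none (default 72, the nominal scanner setting).
#' @return An [rgb_image].
#' @export
read_panicle_image <- function(path, dpi = 72) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  file_dpi <- NA_real_
  if (length(magic) >= 4L && identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi))) file_dpi <- mean(info$dpi)
  } else if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
    px <- jpeg::readJPEG(path)
  } else if (length(magic) >= 2L &&
             (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
              identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    px <- tiff::readTIFF(path, info = TRUE)
    info <- attributes(px)
    if (!is.null(info$x.resolution)) file_dpi <- as.numeric(info$x.resolution)
  } else {
    stop("unrecognised image format: ", path, call. = FALSE)
  }
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 2L) px <- px[, , 1L, drop = FALSE]  # gray + alpha
  vals <- floor(as_plain(px) * 255 + 0.5)
  out_dpi <- if (is.finite(file_dpi)) file_dpi else dpi
  if (dim(vals)[3] == 3L) rgb_image(vals, dpi = out_dpi)
  else structure(vals, dpi = as.numeric(out_dpi), class = "rgb_image")
}

#' Write raster stages to PNG
#'
#' Debug/provenance output: writes a gray image, mask or RGB image to an
#' 8-bit PNG, embedding the dpi when known.
#'
#' @param x A raster object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panicle_png <- function(x, path) {
  dpi <- img_dpi(x)
  dpi <- if (is.finite(dpi)) dpi else NULL
  if (inherits(x, "binary_mask")) {
    png::writePNG(as_plain(x) * 1, path, dpi = dpi)
  } else if (inherits(x, "labeled_mask")) {
    n <- max(1L, n_regions(x))
    png::writePNG(as_plain(x) / n, path, dpi = dpi)
  } else {
    png::writePNG(as_plain(x) / 255, path, dpi = dpi)
  }
  invisible(path)
}
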