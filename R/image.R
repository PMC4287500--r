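# Image carrier and small raster utilities.
#
# Images are plain numeric matrices: rows are image rows (row index grows
# downward, as on screen), columns are image columns, values in [0, 1].
# Binary masks are logical matrices of the same orientation. All indexing is
# 1-based (R convention); "height" is nrow(), "width" is ncol().

#' Validate a grayscale image
#'
#' Checks that `x` is a finite numeric matrix and (optionally) that its values
#' lie in `[0, 1]`, and returns it unchanged. Used at the entry of every
#' raster-stage operation.
#'
#' @param x A numeric matrix.
#' @param range_01 Require values in `[0, 1]`? The curvelet transform accepts
#'   arbitrary finite matrices; enhancement and mask stages require `[0, 1]`.
#' @param arg Name used in error messages.
#' @return `x`, invisibly validated.
#' @export
as_gray_image <- function(x, range_01 = FALSE, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(arg, " must have at least one pixel", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(arg, " contains non-finite values", call. = FALSE)
  }
  if (range_01 && (min(x) < 0 || max(x) > 1)) {
    stop(arg, " values must lie in [0, 1]", call. = FALSE)
  }
  x
}

as_binary_mask <- function(x, arg = "mask") {
  if (is.logical(x) && is.matrix(x)) return(x)
  if (is.numeric(x) && is.matrix(x) && all(x %in% c(0, 1))) {
    return(x > 0.5)
  }
  stop(arg, " must be a logical (or 0/1 numeric) matrix", call. = FALSE)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Flat structuring elements
#'
#' `ellipse_se()` builds the wide-flat elliptical footprint used for the
#' morphological stage: a disc stretched to horizontal semi-extent `a` and
#' vertical semi-extent `b` pixels (default 17x6, matching the lateral band
#' geometry of the tendon). `disc_se()` builds a circular disc of the given
#' radius. Both are 0/1 matrices symmetric under 180-degree rotation.
#'
#' @param a Horizontal (column) semi-extent in pixels.
#' @param b Vertical (row) semi-extent in pixels.
#' @return A `(2b+1) x (2a+1)` numeric 0/1 matrix.
#' @export
ellipse_se <- function(a = 17L, b = 6L) {
  a <- as.integer(a); b <- as.integer(b)
  if (a < 0L || b < 0L) stop("semi-extents must be non-negative", call. = FALSE)
  r <- seq(-b, b); c <- seq(-a, a)
  k <- outer(r / max(b, 1L), c / max(a, 1L), function(y, x) (x^2 + y^2) <= 1)
  storage.mode(k) <- "double"
  k
}

#' @rdname ellipse_se
#' @param radius Disc radius in pixels.
#' @export
disc_se <- function(radius = 8L) ellipse_se(a = radius, b = radius)

se_3x3 <- function() matrix(1, 3L, 3L)

#' Read and write grayscale images and binary masks
#'
#' PNG (via \pkg{png}) and TIFF (via \pkg{tiff}, if installed) round trips.
#' Multichannel input is converted to grayscale by channel averaging. Masks
#' are written as 0/255 8-bit PNG and read back with a 0.5 threshold.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `read_gray()` a numeric matrix in `[0, 1]`; `read_mask()` a logical
#'   matrix; the writers return `path` invisibly.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(x)) == 3L) {
    nch <- dim(x)[3L]
    x <- apply(x[, , seq_len(min(nch, 3L)), drop = FALSE], c(1L, 2L), mean)
  }
  as_gray_image(clip01(x), range_01 = TRUE)
}

#' @rdname read_gray
#' @param image Numeric matrix in `[0, 1]`.
#' @export
write_gray <- function(image, path) {
  image <- as_gray_image(image, range_01 = TRUE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("writing TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::writeTIFF(image, where = path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname read_gray
#' @export
read_mask <- function(path) read_gray(path) > 0.5

#' @rdname read_gray
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  write_gray(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
}
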