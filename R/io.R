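#' Read an RGB image file
#'
#' Reads PNG, TIFF or JPEG via EBImage and returns an 8-bit H x W x 3
#' array. Grayscale files are replicated across channels; an alpha channel,
#' if present, is dropped.
#'
#' @param path File path.
#' @return Integer H x W x 3 array with values in 0..255.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s': no such file", path), call. = FALSE)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)       # width x height (x channels)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  out <- aperm(a, c(2L, 1L, 3L)) * 255   # to row-major H x W x 3
  out <- round(pmin(pmax(out, 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' Write an RGB array or scene as PNG
#' @param img H x W x 3 array in 0..255, or a `fruit_scene`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  img <- as_rgb_array(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (foreground = 255)
#' @param mask 0/1 or logical matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}

#' Read a mask PNG back to a 0/1 integer matrix
#' @param path File path.
#' @return Integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}
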