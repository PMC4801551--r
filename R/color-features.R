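## RGB -> XYZ matrix applied to chromaticity coordinates (r, g, b).
## Each row sums to 1, so achromatic inputs map to X = Y = Z.
.XYZ_M <- matrix(c(
  0.433953, 0.376219, 0.189828,
  0.212671, 0.715160, 0.072169,
  0.017758, 0.109477, 0.872765
), nrow = 3, byrow = TRUE, dimnames = list(c("X", "Y", "Z"), NULL))

## NTSC RGB -> YIQ matrix, applied to raw 8-bit channels.
.YIQ_M <- matrix(c(
  0.2990,  0.5870,  0.1140,
  0.5957, -0.2745, -0.3213,
  0.2115, -0.5226,  0.3111
), nrow = 3, byrow = TRUE, dimnames = list(c("Y", "I", "Q"), NULL))

.check_rgb <- function(rgb) {
  if (!is.numeric(rgb) || anyNA(rgb) || any(!is.finite(rgb))) {
    stop("RGB channel values must be finite numbers", call. = FALSE)
  }
  if (any(rgb < 0) || any(rgb > 255)) {
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  }
  invisible(rgb)
}

.as_rgb_matrix <- function(rgb) {
  if (is.matrix(rgb)) {
    if (ncol(rgb) != 3L) stop("RGB matrix must have 3 columns", call. = FALSE)
    rgb
  } else {
    if (length(rgb) != 3L) stop("an RGB pixel has exactly 3 channels", call. = FALSE)
    matrix(rgb, nrow = 1L)
  }
}

#' Chromaticity coordinates of RGB pixels
#'
#' Normalizes 8-bit RGB channels to chromaticity coordinates
#' `r = R/(R+G+B)` (and likewise `g`, `b`), so that the three coordinates sum
#' to one and all intensity information is removed. A pure black pixel, for
#' which the sum is zero, is mapped to the achromatic point (1/3, 1/3, 1/3);
#' this keeps the mapping continuous with dark grays and avoids exceptional
#' pixels in real scenes.
#'
#' @param rgb A numeric vector of length 3 (one pixel, channels in
#'   \[0, 255\]) or an N x 3 matrix of pixels.
#' @return A vector or matrix of the same shape with columns `r`, `g`, `b`,
#'   each row summing to 1.
#' @examples
#' rgb_normalize(c(255, 0, 0))
#' rgb_normalize(c(0, 0, 0))     # black -> (1/3, 1/3, 1/3)
#' @export
rgb_normalize <- function(rgb) {
  vec <- !is.matrix(rgb)
  m <- .as_rgb_matrix(rgb)
  .check_rgb(m)
  s <- rowSums(m)
  out <- m / s
  out[s == 0, ] <- 1 / 3
  colnames(out) <- c("r", "g", "b")
  if (vec) out[1L, ] else out
}

#' Chromaticity to XYZ tristimulus values
#'
#' Linear map from chromaticity coordinates to the XYZ space. Every row of
#' the conversion matrix sums to one, so achromatic pixels (r = g = b) give
#' X = Y = Z.
#'
#' @param chroma Chromaticity triple (length-3 vector) or N x 3 matrix, as
#'   returned by [rgb_normalize()].
#' @return XYZ triple(s) in the same shape, columns `X`, `Y`, `Z`.
#' @export
rgb_to_xyz <- function(chroma) {
  vec <- !is.matrix(chroma)
  m <- .as_rgb_matrix(chroma)
  if (anyNA(m) || any(!is.finite(m))) {
    stop("chromaticity values must be finite", call. = FALSE)
  }
  out <- m %*% t(.XYZ_M)
  colnames(out) <- c("X", "Y", "Z")
  if (vec) out[1L, ] else out
}

#' Piecewise cube-root companding function of the Lab transform
#'
#' `t^(1/3)` above the breakpoint 0.008856 and the linear segment
#' `7.787 t + 16/116` at or below it.
#' @param t Numeric vector, non-negative.
#' @return Transformed values.
#' @keywords internal
lab_f <- function(t) {
  ifelse(t > 0.008856, t^(1 / 3), 7.787 * t + 16 / 116)
}

#' XYZ to CIELAB
#'
#' Computes `L* = 116 f(Y) - 16`, `a* = 500 (f(X) - f(Y))`,
#' `b* = 200 (f(Y) - f(Z))` with the piecewise companding function [lab_f()].
#' `a*` is the red-green opponent axis: positive for reddish colors, zero for
#' any achromatic pixel, negative for greens — the ripeness-sensitive feature
#' of the pipeline.
#'
#' @param xyz XYZ triple (length-3 vector) or N x 3 matrix.
#' @return Lab triple(s), columns `L`, `a`, `b`.
#' @export
xyz_to_lab <- function(xyz) {
  vec <- !is.matrix(xyz)
  m <- .as_rgb_matrix(xyz)
  if (anyNA(m) || any(!is.finite(m))) {
    stop("XYZ values must be finite", call. = FALSE)
  }
  if (any(m < 0)) {
    stop("XYZ values must be non-negative (cube-root branch undefined)", call. = FALSE)
  }
  fX <- lab_f(m[, 1L]); fY <- lab_f(m[, 2L]); fZ <- lab_f(m[, 3L])
  out <- cbind(L = 116 * fY - 16, a = 500 * (fX - fY), b = 200 * (fY - fZ))
  if (vec) out[1L, ] else out
}

#' Raw RGB to NTSC YIQ
#'
#' Linear NTSC transform applied to the raw 8-bit channels (not to
#' chromaticities). The I (in-phase) component spans the orange-cyan axis and
#' is comparatively robust to brightness changes, which is why it serves as
#' the second chromatic feature.
#'
#' @param rgb Length-3 vector or N x 3 matrix of channels in \[0, 255\].
#' @return YIQ triple(s), columns `Y`, `I`, `Q`.
#' @examples
#' rgb_to_yiq(c(255, 0, 0))   # I = 151.9035
#' @export
rgb_to_yiq <- function(rgb) {
  vec <- !is.matrix(rgb)
  m <- .as_rgb_matrix(rgb)
  .check_rgb(m)
  out <- m %*% t(.YIQ_M)
  colnames(out) <- c("Y", "I", "Q")
  if (vec) out[1L, ] else out
}

#' Feature image container
#'
#' @param values Numeric H x W matrix of raw feature values.
#' @param channel Either `"a_star"`, `"I"`, or a tag for derived images
#'   (e.g. `"fused"`).
#' @param normalized Optional H x W matrix of min-max normalized values in
#'   \[0, 1\] (populated by [normalize_feature()]).
#' @return An object of class `feature_image`.
#' @export
feature_image <- function(values, channel, normalized = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  structure(list(values = values, channel = channel, normalized = normalized),
            class = "feature_image")
}

#' @export
print.feature_image <- function(x, ...) {
  cat(sprintf("<feature_image> channel=%s  %d x %d  range [%.4g, %.4g]%s\n",
              x$channel, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values),
              if (is.null(x$normalized)) "" else "  (normalized)"))
  invisible(x)
}

#' Extract the a* and I chromatic feature images
#'
#' Applies the two conversion chains pixelwise to an 8-bit RGB image: RGB ->
#' chromaticity -> XYZ -> Lab for the a* component, and RGB -> YIQ for the
#' I component. Both outputs have the same height and width as the input.
#'
#' @param img An H x W x 3 numeric array with channel values in \[0, 255\],
#'   or a `fruit_scene` object (its image is used).
#' @return A list with elements `a_star` and `I`, both [feature_image()]s.
#' @export
extract_feature_images <- function(img) {
  img <- as_rgb_array(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  px <- cbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]), as.vector(img[, , 3L]))
  lab <- xyz_to_lab(rgb_to_xyz(rgb_normalize(px)))
  yiq <- rgb_to_yiq(px)
  list(
    a_star = feature_image(matrix(lab[, "a"], h, w), "a_star"),
    I      = feature_image(matrix(yiq[, "I"], h, w), "I")
  )
}

#' Min-max normalize a feature image to \[0, 1\]
#'
#' Rescales so the minimum maps to 0 and the maximum to 1, the bounded form
#' required for the range-based fusion weight to be a convex mixing
#' proportion. A constant image maps to all zeros.
#'
#' @param f A [feature_image()] or a bare numeric matrix.
#' @return The `feature_image` with its `normalized` field populated (a bare
#'   matrix input returns a `feature_image` with channel `"raw"`).
#' @export
normalize_feature <- function(f) {
  if (is.matrix(f)) f <- feature_image(f, "raw")
  if (!inherits(f, "feature_image")) stop("not a feature_image", call. = FALSE)
  v <- f$values
  if (anyNA(v) || any(!is.finite(v))) stop("feature values must be finite", call. = FALSE)
  rng <- range(v)
  f$normalized <- if (rng[1L] == rng[2L]) {
    matrix(0, nrow(v), ncol(v))
  } else {
    (v - rng[1L]) / (rng[2L] - rng[1L])
  }
  f
}

#' Coerce supported inputs to an H x W x 3 RGB array
#' @param img Array, `fruit_scene`, or file path.
#' @return Numeric H x W x 3 array in \[0, 255\].
#' @keywords internal
as_rgb_array <- function(img) {
  if (inherits(img, "fruit_scene")) img <- img$image
  if (is.character(img) && length(img) == 1L) img <- read_rgb_image(img)
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  if (any(dim(img)[1:2] < 1L) || length(img) == 0L) stop("empty image", call. = FALSE)
  .check_rgb(img)
  img
}
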