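.norm_values <- function(x, arg = "image") {
  if (inherits(x, "feature_image")) {
    x <- if (!is.null(x$normalized)) x$normalized else x$values
  }
  if (!is.matrix(x) || !is.numeric(x)) stop(sprintf("%s must be a numeric matrix", arg), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop(sprintf("%s has non-finite values", arg), call. = FALSE)
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9) {
    stop(sprintf("%s must be normalized to [0, 1]; see normalize_feature()", arg), call. = FALSE)
  }
  x
}

#' Range-based fusion weight
#'
#' Forms the elementwise maximum `L_max` of the two normalized feature
#' images and returns its dynamic range `d = max(L_max) - min(L_max)`, the
#' mixing proportion used to combine the two wavelet decompositions. With
#' inputs in \[0, 1\], `d` always lies in \[0, 1\].
#'
#' @param A,B Normalized feature images ([feature_image()] with the
#'   `normalized` field set, or bare matrices in \[0, 1\]) of equal shape.
#' @return An object of class `fusion_weight` with fields `d`, `x_min`,
#'   `x_max`.
#' @export
compute_fusion_weight <- function(A, B) {
  a <- .norm_values(A, "A"); b <- .norm_values(B, "B")
  if (!identical(dim(a), dim(b))) stop("A and B must have the same shape", call. = FALSE)
  lmax <- pmax(a, b)
  x_min <- min(lmax); x_max <- max(lmax)
  structure(list(d = x_max - x_min, x_min = x_min, x_max = x_max),
            class = "fusion_weight")
}

#' @export
print.fusion_weight <- function(x, ...) {
  cat(sprintf("<fusion_weight> d = %.6f  (L_max range [%.6f, %.6f])\n",
              x$d, x$x_min, x$x_max))
  invisible(x)
}

#' Convex combination of two wavelet decompositions
#'
#' Sets every coefficient grid (approximation and all detail subbands) of
#' the output to `(1 - d) * C1 + d * C2`.
#'
#' @param C1,C2 Structurally identical `wavelet_coeffs` objects.
#' @param w A `fusion_weight`, or a bare number in \[0, 1\].
#' @return A fused `wavelet_coeffs` object.
#' @export
fuse_coefficients <- function(C1, C2, w) {
  stopifnot(inherits(C1, "wavelet_coeffs"), inherits(C2, "wavelet_coeffs"))
  if (!.same_structure(C1, C2)) {
    stop("C1 and C2 must share levels, wavelet, boundary mode and shapes", call. = FALSE)
  }
  d <- if (inherits(w, "fusion_weight")) w$d else w
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d < 0 || d > 1) {
    stop("fusion weight must be a single number in [0, 1]", call. = FALSE)
  }
  .map_coeffs(C1, C2, function(x, y) (1 - d) * x + d * y)
}

#' Pixel-level wavelet fusion of two feature images
#'
#' The fusion path of the recognition pipeline: compute the range-based
#' weight `d` from the two normalized images, decompose both with a
#' multilevel 2-D wavelet transform, mix every coefficient as
#' `(1 - d) C1 + d C2`, reconstruct, and clip to \[0, 1\]. Because one
#' scalar weight is applied to all coefficients of a linear invertible
#' transform, the result equals the pixelwise convex combination
#' `(1 - d) A + d B` up to floating-point error; the decomposition is kept
#' as the method's structure and for the per-subband variant.
#'
#' @inheritParams compute_fusion_weight
#' @param levels,wavelet,boundary Passed to [wavelet_decompose()].
#' @param per_subband_weight If `TRUE`, a separate weight is computed for
#'   each subband pair by applying the same range rule to the coefficient
#'   grids (clipped to \[0, 1\]), instead of one global spatial-domain `d`.
#'   Off by default.
#' @return A [feature_image()] with channel `"fused"`, values in \[0, 1\],
#'   and attribute `"fusion_weight"` holding the global weight object.
#' @export
fuse_images <- function(A, B, levels = 3L, wavelet = "db2",
                        boundary = c("periodization", "symmetric"),
                        per_subband_weight = FALSE) {
  boundary <- match.arg(boundary)
  a <- .norm_values(A, "A"); b <- .norm_values(B, "B")
  if (!identical(dim(a), dim(b))) stop("A and B must have the same shape", call. = FALSE)
  w <- compute_fusion_weight(a, b)
  c1 <- wavelet_decompose(a, levels, wavelet, boundary)
  c2 <- wavelet_decompose(b, levels, wavelet, boundary)
  fused <- if (isTRUE(per_subband_weight)) {
    .map_coeffs(c1, c2, function(x, y) {
      lm <- pmax(x, y)
      ds <- min(1, max(0, max(lm) - min(lm)))
      (1 - ds) * x + ds * y
    })
  } else {
    fuse_coefficients(c1, c2, w)
  }
  rec <- wavelet_reconstruct(fused)
  rec <- pmin(pmax(rec, 0), 1)
  out <- feature_image(rec, "fused", normalized = rec)
  attr(out, "fusion_weight") <- w
  out
}

#' Simple averaging fusion baseline
#'
#' Direct pixelwise arithmetic mean of the two normalized feature images,
#' the plain combination strategy the wavelet path is compared against.
#'
#' @inheritParams compute_fusion_weight
#' @return A [feature_image()] with channel `"simple_fusion"`.
#' @export
simple_fusion_baseline <- function(A, B) {
  a <- .norm_values(A, "A"); b <- .norm_values(B, "B")
  if (!identical(dim(a), dim(b))) stop("A and B must have the same shape", call. = FALSE)
  v <- (a + b) / 2
  feature_image(v, "simple_fusion", normalized = v)
}
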