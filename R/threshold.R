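#' Quantize a normalized image to the 8-bit gray scale
#'
#' Maps \[0, 1\] values to integers 0..255 by scaling and rounding.
#' Thresholds are computed on this scale.
#'
#' @param x Numeric matrix in \[0, 1\] or a [feature_image()].
#' @return Integer matrix with values in 0..255.
#' @export
gray_quantize <- function(x) {
  x <- .norm_values(x, "image")
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

.check_gray <- function(img) {
  if (inherits(img, "feature_image")) {
    img <- if (!is.null(img$normalized)) gray_quantize(img) else img$values
  }
  if (!is.matrix(img) && is.numeric(img)) img <- as.matrix(img)
  if (!is.numeric(img) || length(img) == 0L) stop("empty or non-numeric image", call. = FALSE)
  if (anyNA(img) || any(!is.finite(img))) stop("gray values must be finite", call. = FALSE)
  img
}

#' Iterative (intermeans) threshold selection
#'
#' Starts from the midpoint of the gray range, `T0 = (T_max + T_min) / 2`,
#' splits the pixels at the current threshold into class A (values above)
#' and class B (values at or below), and replaces the threshold by the mean
#' of the two class averages until it moves by less than `tolerance`. Pixels
#' exactly at the threshold belong to class B, matching the final
#' binarization's `<=` convention. A constant image is degenerate: the
#' constant itself is returned and flagged.
#'
#' @param img Numeric matrix of gray values (any real scale; the pipeline
#'   uses 0..255).
#' @param tolerance Convergence tolerance on the threshold (default 0.5, half
#'   a gray level: sub-quantization precision is meaningless on an 8-bit
#'   scale).
#' @param max_iter Iteration cap (default 256).
#' @return List with `T_m` (the threshold), `iterations` (the trace of
#'   thresholds, starting at `T0`), `T_max`, `T_min`, `T_A`, `T_B` (final
#'   class means), `W` (final count of pixels above `T_m`), and `degenerate`.
#' @export
iterative_threshold <- function(img, tolerance = 0.5, max_iter = 256L) {
  v <- as.vector(.check_gray(img))
  tmax <- max(v); tmin <- min(v)
  if (tmax == tmin) {
    return(list(T_m = tmax, iterations = tmax, T_max = tmax, T_min = tmin,
                T_A = tmax, T_B = tmax, W = 0L, degenerate = TRUE))
  }
  tk <- (tmax + tmin) / 2
  trace <- tk
  ta <- tb <- w <- NA_real_
  for (k in seq_len(max_iter)) {
    above <- v > tk
    w <- sum(above)
    ta <- if (w > 0L) mean(v[above]) else tk
    tb <- if (w < length(v)) mean(v[!above]) else tk
    tnew <- (ta + tb) / 2
    trace <- c(trace, tnew)
    if (abs(tnew - tk) < tolerance) {
      tk <- tnew
      break
    }
    tk <- tnew
  }
  list(T_m = tk, iterations = trace, T_max = tmax, T_min = tmin,
       T_A = ta, T_B = tb, W = as.integer(sum(v > tk)), degenerate = FALSE)
}

#' Otsu's threshold by between-class variance
#'
#' Searches all 256 candidate 8-bit levels `t` for the split (class 0:
#' values `<= t`, class 1: values `> t`) maximizing the between-class
#' variance `w0 w1 (mu0 - mu1)^2`. Ties are broken by the lowest maximizing
#' level, making the result deterministic and independent of pixel order.
#'
#' @param img Integer matrix with values in 0..255 (real values are rounded).
#' @return The threshold as a single number; a constant image returns the
#'   constant with attribute `degenerate = TRUE`.
#' @export
otsu_threshold <- function(img) {
  v <- as.vector(.check_gray(img))
  v <- as.integer(round(v))
  if (any(v < 0L) || any(v > 255L)) {
    stop("otsu_threshold expects 8-bit gray values in 0..255", call. = FALSE)
  }
  if (max(v) == min(v)) {
    return(structure(as.numeric(v[1L]), degenerate = TRUE))
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  p <- counts / n
  lev <- 0:255
  w0 <- cumsum(p)                 # P(value <= t), t = 0..255
  mu <- cumsum(p * lev)           # E[value * 1(value <= t)]
  mut <- mu[256L]
  w1 <- 1 - w0
  ## between-class variance; undefined (0/0) where a class is empty
  num <- (mut * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  as.numeric(lev[which.max(sigma_b)])    # which.max takes the lowest tie
}

#' Final segmentation threshold: the smaller of the two
#'
#' Combination rule for the adaptive threshold: when the iterative result
#' `T_m` is greater than or equal to Otsu's `T_n`, `T_n` is the final
#' threshold, otherwise `T_m` — i.e. the minimum of the two.
#'
#' @param T_m Iterative (intermeans) threshold.
#' @param T_n Otsu threshold.
#' @return The final threshold `T_f`.
#' @export
final_threshold <- function(T_m, T_n) {
  stopifnot(is.finite(T_m), is.finite(T_n))
  if (T_m >= T_n) T_n else T_m
}

#' Binarize a gray image at a threshold
#'
#' With `polarity = "high"` (default) foreground is the bright side,
#' `values > T_f`; with `polarity = "low"` it is `values <= T_f`. The fused
#' feature image renders ripe fruit bright, hence the default; the low
#' polarity keeps the opposite convention available.
#'
#' @param img Numeric matrix of gray values.
#' @param T_f Threshold.
#' @param polarity `"high"` or `"low"`.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(img, T_f, polarity = c("high", "low")) {
  polarity <- match.arg(polarity)
  img <- .check_gray(img)
  stopifnot(is.finite(T_f))
  m <- if (polarity == "high") img > T_f else img <= T_f
  matrix(as.integer(m), nrow(img), ncol(img))
}

#' Adaptive threshold report for a gray image
#'
#' Runs both threshold selectors and the combination rule on one image and
#' collects the full trace.
#'
#' @param img Integer matrix of 8-bit gray values (see [gray_quantize()]).
#' @param tolerance Passed to [iterative_threshold()].
#' @return An object of class `threshold_report` with fields `T_m`, `T_n`,
#'   `T_f`, `iterations`, `T_max`, `T_min`, `T_A`, `T_B`, `W`, `degenerate`.
#' @export
threshold_report <- function(img, tolerance = 0.5) {
  img <- .check_gray(img)
  it <- iterative_threshold(img, tolerance = tolerance)
  tn <- otsu_threshold(img)
  structure(list(
    T_m = it$T_m, T_n = as.numeric(tn), T_f = final_threshold(it$T_m, tn),
    iterations = it$iterations, T_max = it$T_max, T_min = it$T_min,
    T_A = it$T_A, T_B = it$T_B, W = it$W,
    degenerate = it$degenerate || isTRUE(attr(tn, "degenerate"))
  ), class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> T_m = %.2f (iterative, %d step%s)  T_n = %.0f (Otsu)  ->  T_f = %.2f%s\n",
              x$T_m, length(x$iterations), if (length(x$iterations) == 1L) "" else "s",
              x$T_n, x$T_f, if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Serialize a threshold report to JSON
#' @param x A `threshold_report`.
#' @return A JSON string.
#' @export
threshold_report_json <- function(x) {
  stopifnot(inherits(x, "threshold_report"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
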