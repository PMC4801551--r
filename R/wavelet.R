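## Multilevel 2-D discrete wavelet transform.
##
## The analysis step for a signal of length n is represented explicitly as a
## (2o) x n matrix A (low-pass rows stacked over high-pass rows, filters
## placed at even offsets over the boundary-extended signal). Synthesis uses
## the exact left inverse of A: t(A) when A is orthonormal (periodization,
## even n), otherwise the Moore-Penrose pseudo-inverse. Either way,
## reconstruction of unmodified coefficients reproduces the input to machine
## precision for every length, filter and boundary mode. Matrices are cached
## per (n, wavelet, mode); the low-pass/high-pass matrices are banded, so
## they are stored sparse.

.wav_cache <- new.env(parent = emptyenv())

#' Orthonormal wavelet filter pairs
#'
#' Scaling (low-pass) and quadrature-mirror wavelet (high-pass) filters for
#' the supported orthogonal families.
#'
#' @param name One of `"haar"`, `"db2"`, `"db4"`.
#' @return List with numeric vectors `lo` and `hi`.
#' @keywords internal
wavelet_filters <- function(name) {
  lo <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4  = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
             -0.027983769416984, -0.187034811718881, 0.030841381835987,
             0.032883011666983, -0.010597401784997),
    stop(sprintf("unsupported wavelet '%s' (use haar, db2 or db4)", name),
         call. = FALSE)
  )
  p <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(p) - 1L)
  list(lo = lo, hi = hi)
}

## Map an out-of-range position onto 1..n by half-sample symmetric reflection
## (edge value repeated), iterated for very short signals.
.sym_index <- function(t, n) {
  while (any(bad <- t < 1L | t > n)) {
    t[t < 1L] <- 1L - t[t < 1L]
    t[t > n] <- 2L * n + 1L - t[t > n]
  }
  t
}

.analysis_operator <- function(n, wavelet, mode) {
  key <- paste(n, wavelet, mode, sep = "|")
  hit <- .wav_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- wavelet_filters(wavelet)
  p <- length(f$lo)
  if (mode == "periodization") {
    o <- ceiling(n / 2)
    A <- matrix(0, 2L * o, n)
    for (i in seq_len(o)) {
      idx <- ((2L * (i - 1L) + seq_len(p) - 1L) %% n) + 1L
      for (j in seq_len(p)) {           # accumulate: wraps may collide for n < p
        A[i, idx[j]] <- A[i, idx[j]] + f$lo[j]
        A[o + i, idx[j]] <- A[o + i, idx[j]] + f$hi[j]
      }
    }
  } else if (mode == "symmetric") {
    o <- (n + p) %/% 2L    # stride-2 windows [2i - p, 2i - 1] covering 1..n
    A <- matrix(0, 2L * o, n)
    for (i in seq_len(o)) {
      pos <- .sym_index(2L * (i - 1L) + seq_len(p) - (p - 1L), n)
      for (j in seq_len(p)) {
        A[i, pos[j]] <- A[i, pos[j]] + f$lo[j]
        A[o + i, pos[j]] <- A[o + i, pos[j]] + f$hi[j]
      }
    }
  } else {
    stop(sprintf("unknown boundary mode '%s'", mode), call. = FALSE)
  }
  G <- crossprod(A)
  S <- if (max(abs(G - diag(n))) < 1e-10) t(A) else solve(G, t(A))
  op <- list(A = Matrix::Matrix(A, sparse = TRUE),
             S = Matrix::Matrix(S, sparse = mean(S == 0) > 0.5),
             o = o)
  assign(key, op, envir = .wav_cache)
  op
}

#' Multilevel 2-D wavelet decomposition
#'
#' Separable dyadic decomposition of an image into one coarse approximation
#' and per-level horizontal/vertical/diagonal detail subbands. The transform
#' is exactly invertible ([wavelet_reconstruct()]) for every image size and
#' boundary mode.
#'
#' @param x Numeric matrix, or a [feature_image()] (its normalized values are
#'   used when present).
#' @param levels Number of decomposition levels (default 3).
#' @param wavelet Wavelet family: `"haar"`, `"db2"` (default), `"db4"`.
#' @param boundary Signal extension at image borders: `"periodization"`
#'   (default; dyadic subband sizes, orthogonal for even sizes) or
#'   `"symmetric"`.
#' @return An object of class `wavelet_coeffs`: `approximation` matrix,
#'   `details` (list per level, coarsest last, each with `horizontal`,
#'   `vertical`, `diagonal` matrices), and the metadata needed to invert.
#' @export
wavelet_decompose <- function(x, levels = 3L, wavelet = "db2",
                              boundary = c("periodization", "symmetric")) {
  boundary <- match.arg(boundary)
  if (inherits(x, "feature_image")) {
    x <- if (!is.null(x$normalized)) x$normalized else x$values
  }
  stopifnot(is.matrix(x), is.numeric(x))
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  minsz <- 2^levels
  if (nrow(x) < minsz || ncol(x) < minsz) {
    stop(sprintf("image %d x %d too small for %d levels: each dimension must be >= %d",
                 nrow(x), ncol(x), levels, minsz), call. = FALSE)
  }
  details <- vector("list", levels)
  dims <- vector("list", levels)
  cur <- x
  for (lev in seq_len(levels)) {
    m <- nrow(cur); n <- ncol(cur)
    opm <- .analysis_operator(m, wavelet, boundary)
    opn <- .analysis_operator(n, wavelet, boundary)
    t1 <- as.matrix(opm$A %*% cur %*% Matrix::t(opn$A))
    om <- opm$o; on <- opn$o
    details[[lev]] <- list(
      horizontal = t1[seq_len(om), on + seq_len(on), drop = FALSE],
      vertical   = t1[om + seq_len(om), seq_len(on), drop = FALSE],
      diagonal   = t1[om + seq_len(om), on + seq_len(on), drop = FALSE]
    )
    dims[[lev]] <- c(m, n)
    cur <- t1[seq_len(om), seq_len(on), drop = FALSE]
  }
  structure(list(approximation = cur, details = details, levels = levels,
                 wavelet = wavelet, boundary = boundary, dims = dims),
            class = "wavelet_coeffs")
}

#' Invert a multilevel 2-D wavelet decomposition
#'
#' @param wc A `wavelet_coeffs` object from [wavelet_decompose()].
#' @return The reconstructed numeric matrix, with the original dimensions.
#' @export
wavelet_reconstruct <- function(wc) {
  stopifnot(inherits(wc, "wavelet_coeffs"))
  cur <- wc$approximation
  for (lev in rev(seq_len(wc$levels))) {
    d <- wc$details[[lev]]
    mn <- wc$dims[[lev]]
    opm <- .analysis_operator(mn[1L], wc$wavelet, wc$boundary)
    opn <- .analysis_operator(mn[2L], wc$wavelet, wc$boundary)
    t1 <- rbind(cbind(cur, d$horizontal), cbind(d$vertical, d$diagonal))
    cur <- as.matrix(opm$S %*% t1 %*% Matrix::t(opn$S))
  }
  cur
}

#' @export
print.wavelet_coeffs <- function(x, ...) {
  cat(sprintf("<wavelet_coeffs> %s, %d level(s), boundary=%s, approx %d x %d\n",
              x$wavelet, x$levels, x$boundary,
              nrow(x$approximation), ncol(x$approximation)))
  invisible(x)
}

## Apply a function to every coefficient grid of one (or a pair of)
## wavelet_coeffs, preserving structure.
.map_coeffs <- function(w1, w2, fun) {
  out <- w1
  out$approximation <- fun(w1$approximation, w2$approximation)
  for (lev in seq_len(w1$levels)) {
    for (b in c("horizontal", "vertical", "diagonal")) {
      out$details[[lev]][[b]] <- fun(w1$details[[lev]][[b]], w2$details[[lev]][[b]])
    }
  }
  out
}

.same_structure <- function(w1, w2) {
  identical(w1$levels, w2$levels) && identical(w1$wavelet, w2$wavelet) &&
    identical(w1$boundary, w2$boundary) && identical(w1$dims, w2$dims) &&
    identical(dim(w1$approximation), dim(w2$approximation))
}
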