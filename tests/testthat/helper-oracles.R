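# Independent brute-force oracles, written step by step from the method's
# textual description so they share no code with the package internals.

# Intermeans threshold: explicit loop, class A strictly above, class B at or
# below, stop when the threshold moves less than tol. Returns the full trace.
oracle_iterative <- function(v, tol = 0.5, max_iter = 256L) {
  tmax <- max(v); tmin <- min(v)
  if (tmax == tmin) return(list(T_m = tmax, trace = tmax))
  tk <- (tmax + tmin) / 2
  trace <- tk
  for (k in seq_len(max_iter)) {
    A <- v[v > tk]
    B <- v[v <= tk]
    TA <- if (length(A) > 0) sum(A) / length(A) else tk
    TB <- if (length(B) > 0) sum(B) / length(B) else tk
    tnew <- (TA + TB) / 2
    trace <- c(trace, tnew)
    if (abs(tnew - tk) < tol) { tk <- tnew; break }
    tk <- tnew
  }
  list(T_m = tk, trace = trace)
}

# Otsu: exhaustive search over all 256 candidate levels, recomputing class
# weights and means from scratch at every level; lowest maximizer wins.
oracle_otsu <- function(v) {
  v <- as.integer(round(v))
  best_t <- NA_integer_
  best_s <- -Inf
  n <- length(v)
  for (t in 0:255) {
    c0 <- v[v <= t]; c1 <- v[v > t]
    if (length(c0) == 0L || length(c1) == 0L) next
    w0 <- length(c0) / n; w1 <- length(c1) / n
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  if (is.na(best_t)) v[1L] else best_t
}

# Random 8-bit test image with a fixed seed.
rand_gray <- function(seed, nr = 16L, nc = 16L, lo = 0L, hi = 255L) {
  with_seed(seed, matrix(sample(lo:hi, nr * nc, replace = TRUE), nr, nc))
}

rand_norm_image <- function(seed, nr = 64L, nc = 64L) {
  with_seed(seed, {
    x <- matrix(stats::runif(nr * nc), nr, nc)
    (x - min(x)) / (max(x) - min(x))
  })
}

# Build a uniform-color RGB array.
uniform_rgb <- function(r, g, b, nr = 4L, nc = 5L) {
  arr <- array(0, c(nr, nc, 3L))
  arr[, , 1L] <- r; arr[, , 2L] <- g; arr[, , 3L] <- b
  arr
}

with_seed <- fruitfusion:::with_seed
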