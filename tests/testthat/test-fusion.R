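test_that("the fusion weight is the dynamic range of the elementwise maximum", {
  expect_equal(compute_fusion_weight(matrix(0.4, 3, 3), matrix(0.4, 3, 3))$d, 0)
  w <- compute_fusion_weight(matrix(c(0, 0.2), 1, 2), matrix(c(0.1, 0.6), 1, 2))
  expect_equal(w$x_min, 0.1)
  expect_equal(w$x_max, 0.6)
  expect_equal(w$d, 0.5)
  # a full-range image forces d = 1 when the other image vanishes with it
  a <- matrix(seq(0, 1, length.out = 12), 3, 4)
  b <- a / 2
  expect_equal(compute_fusion_weight(a, b)$d, 1)
  expect_error(compute_fusion_weight(matrix(0.5, 2, 2), matrix(0.5, 3, 3)), "same shape")
  expect_error(compute_fusion_weight(matrix(1.4, 2, 2), matrix(0.5, 2, 2)), "normalized")
})

test_that("the weight is symmetric in its arguments", {
  with_seed(31, {
    for (i in 1:10) {
      a <- matrix(runif(20), 4, 5)
      b <- matrix(runif(20), 4, 5)
      expect_identical(compute_fusion_weight(a, b)$d, compute_fusion_weight(b, a)$d)
    }
  })
})

test_that("wavelet fusion equals the pixelwise convex combination", {
  with_seed(32, {
    for (i in 1:20) {
      a <- rand_norm_image(1000 + i)
      b <- rand_norm_image(2000 + i)
      d <- compute_fusion_weight(a, b)$d
      f <- fuse_images(a, b)
      direct <- (1 - d) * a + d * b
      expect_lt(max(abs(f$values - direct)), 1e-6)
      # convexity: every output pixel between the two inputs
      expect_true(all(f$values >= pmin(a, b) - 1e-6 & f$values <= pmax(a, b) + 1e-6))
    }
  })
})

test_that("fusion endpoints return a source image and A = B is a fixed point", {
  a <- rand_norm_image(41)
  # B dominated everywhere by a constant-1 A-side maximum: d = 0, output = A
  f0 <- fuse_images(a, matrix(1, 64, 64))
  expect_equal(attr(f0, "fusion_weight")$d, 0)
  expect_lt(max(abs(f0$values - a)), 1e-6)
  # A constant 0 against a full-range B: d = 1, output = B
  b <- rand_norm_image(42)
  f1 <- fuse_images(matrix(0, 64, 64), b)
  expect_equal(attr(f1, "fusion_weight")$d, 1)
  expect_lt(max(abs(f1$values - b)), 1e-6)
  ff <- fuse_images(a, a)
  expect_lt(max(abs(ff$values - a)), 1e-8)
})

test_that("per-subband weighting still reproduces both degenerate endpoints", {
  a <- rand_norm_image(43)
  ff <- fuse_images(a, a, per_subband_weight = TRUE)
  expect_lt(max(abs(ff$values - a)), 1e-8)
  expect_equal(dim(ff$values), dim(a))
})

test_that("the simple baseline is the pixel average", {
  a <- rand_norm_image(44, 8, 8)
  expect_equal(simple_fusion_baseline(a, a)$values, a)
  expect_equal(simple_fusion_baseline(matrix(0, 4, 4), matrix(1, 4, 4))$values,
               matrix(0.5, 4, 4))
  expect_equal(simple_fusion_baseline(matrix(c(0, 1), 1, 2), matrix(c(1, 0), 1, 2))$values,
               matrix(0.5, 1, 2))
  expect_error(simple_fusion_baseline(matrix(0, 2, 2), matrix(0, 3, 3)), "same shape")
})
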