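test_that("chromaticity normalization handles equal, pure and black pixels", {
  expect_equal(unname(rgb_normalize(c(100, 100, 100))), rep(1 / 3, 3))
  expect_equal(unname(rgb_normalize(c(255, 0, 0))), c(1, 0, 0))
  expect_equal(unname(rgb_normalize(c(0, 0, 0))), rep(1 / 3, 3))
  m <- rgb_normalize(matrix(c(10, 20, 30, 0, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(unname(rowSums(m)), c(1, 1))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(rgb_normalize(c(-1, 0, 0)), "0, 255")
  expect_error(rgb_normalize(c(NA, 0, 0)), "finite")
  expect_error(rgb_normalize(c(300, 0, 0)), "0, 255")
})

test_that("chromaticity to XYZ uses the printed coefficients, rows summing to one", {
  # pure red chromaticity picks out the first matrix column
  expect_equal(unname(rgb_to_xyz(c(1, 0, 0))), c(0.433953, 0.212671, 0.017758))
  # each row sums to 1, so the achromatic point is fixed
  expect_equal(unname(rgb_to_xyz(rep(1 / 3, 3))), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(unname(rgb_to_xyz(c(0, 0, 0))), c(0, 0, 0))
  # row sums: the all-ones vector is a fixed point of the matrix
  expect_equal(unname(rgb_to_xyz(c(1, 1, 1))), c(1, 1, 1), tolerance = 1e-6)
})

test_that("XYZ to Lab matches the closed-form values and zeroes chroma for grays", {
  expect_equal(unname(xyz_to_lab(c(1, 1, 1))), c(100, 0, 0))
  expect_equal(unname(xyz_to_lab(c(0, 0, 0))), c(0, 0, 0))
  v <- 0.333333
  lab <- xyz_to_lab(rep(v, 3))
  expect_equal(unname(lab), c(116 * v^(1 / 3) - 16, 0, 0))
  expect_equal(unname(lab)[1], 64.43, tolerance = 1e-3)
  expect_error(xyz_to_lab(c(-0.1, 0.2, 0.2)), "non-negative")
})

test_that("the companding function is continuous at its breakpoint", {
  t0 <- 0.008856
  f <- fruitfusion:::lab_f
  expect_equal(f(t0 + 1e-12), f(t0), tolerance = 1e-3)
  expect_equal(f(t0), 7.787 * t0 + 16 / 116)
  expect_equal(f(1), 1)
})

test_that("YIQ transform uses raw channels with the printed coefficients", {
  expect_equal(unname(rgb_to_yiq(c(0, 0, 0))), c(0, 0, 0))
  # white: I = 255 * (0.5957 - 0.2745 - 0.3213)
  expect_equal(unname(rgb_to_yiq(c(255, 255, 255)))[2], -0.0255, tolerance = 1e-9)
  expect_equal(unname(rgb_to_yiq(c(255, 0, 0))), c(76.2450, 151.9035, 53.9325))
})

test_that("YIQ transform is linear in the pixel", {
  with_seed(11, {
    for (i in 1:20) {
      p <- runif(3, 0, 255)
      a <- runif(1)
      expect_equal(unname(rgb_to_yiq(a * p)), unname(a * rgb_to_yiq(p)),
                   tolerance = 1e-9)
    }
  })
})

test_that("feature extraction preserves shape and separates red from gray and green", {
  img <- uniform_rgb(120, 120, 120, 2, 3)
  f <- extract_feature_images(img)
  expect_equal(dim(f$a_star$values), c(2, 3))
  expect_equal(dim(f$I$values), c(2, 3))
  expect_equal(f$a_star$values, matrix(0, 2, 3))   # grays have a* exactly 0

  red <- extract_feature_images(uniform_rgb(255, 0, 0))
  expect_true(all(red$a_star$values > 0))
  expect_equal(length(unique(as.vector(red$a_star$values))), 1L)
  expect_equal(red$I$values, matrix(151.9035, 4, 5))

  green <- extract_feature_images(uniform_rgb(0, 255, 0))
  expect_true(all(green$a_star$values < 0))
  expect_error(extract_feature_images(array(0, c(0, 3, 3))), "empty")
})

test_that("min-max normalization is bounded, idempotent, and zero on constants", {
  f <- normalize_feature(matrix(c(10, 20, 30), 1, 3))
  expect_equal(f$normalized, matrix(c(0, 0.5, 1), 1, 3))
  cst <- normalize_feature(matrix(7, 3, 3))
  expect_equal(cst$normalized, matrix(0, 3, 3))
  full <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  expect_equal(normalize_feature(full)$normalized, full)
  with_seed(3, {
    for (i in 1:10) {
      x <- matrix(rnorm(30), 5, 6)
      n1 <- normalize_feature(x)$normalized
      expect_true(min(n1) >= 0 && max(n1) <= 1)
      expect_equal(normalize_feature(n1)$normalized, n1)
    }
  })
  expect_error(normalize_feature(matrix(c(1, Inf), 1, 2)), "finite")
})
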