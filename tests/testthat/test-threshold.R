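test_that("intermeans threshold reproduces hand-iterated two-level cases", {
  r <- iterative_threshold(matrix(c(0, 255), 1, 2))
  expect_equal(r$T_m, 127.5)
  expect_equal(r$iterations, c(127.5, 127.5))
  expect_equal(r$T_A, 255)
  expect_equal(r$T_B, 0)

  r2 <- iterative_threshold(matrix(c(rep(0, 10), rep(100, 10)), 4, 5))
  expect_equal(r2$T_m, 50)
  expect_equal(r2$iterations, c(50, 50))

  rc <- iterative_threshold(matrix(42, 3, 3))
  expect_equal(rc$T_m, 42)
  expect_true(rc$degenerate)
  expect_error(iterative_threshold(matrix(numeric(0), 0, 0)), "empty")
})

test_that("intermeans threshold matches the step-by-step oracle on random images", {
  for (i in 1:50) {
    img <- rand_gray(100 + i)
    got <- iterative_threshold(img)
    want <- oracle_iterative(as.vector(img))
    expect_identical(got$iterations, want$trace)
    expect_identical(got$T_m, want$T_m)
    expect_lte(length(got$iterations), 256L)
  }
})

test_that("intermeans threshold is invariant to pixel order", {
  img <- rand_gray(7, 12, 12)
  shuffled <- with_seed(8, matrix(sample(as.vector(img)), 12, 12))
  expect_identical(iterative_threshold(img)$T_m, iterative_threshold(shuffled)$T_m)
})

test_that("Otsu matches exhaustive between-class-variance search", {
  for (i in 1:50) {
    img <- rand_gray(300 + i)
    expect_identical(as.numeric(otsu_threshold(img)), as.numeric(oracle_otsu(as.vector(img))))
  }
  # narrow-range images exercise empty-class candidates
  for (i in 1:10) {
    img <- rand_gray(400 + i, lo = 100L, hi = 110L)
    expect_identical(as.numeric(otsu_threshold(img)), as.numeric(oracle_otsu(as.vector(img))))
  }
})

test_that("Otsu separates a two-value image like the oracle and flags constants", {
  img <- matrix(c(rep(0L, 10), rep(255L, 10)), 4, 5)
  t1 <- otsu_threshold(img)
  expect_true(t1 >= 0 && t1 < 255)
  expect_identical(as.numeric(t1), as.numeric(oracle_otsu(as.vector(img))))
  # class assignment at the returned threshold matches the oracle's
  expect_identical(img <= t1, img <= oracle_otsu(as.vector(img)))
  tc <- otsu_threshold(matrix(9L, 2, 2))
  expect_equal(as.numeric(tc), 9)
  expect_true(attr(tc, "degenerate"))
})

test_that("the final threshold is the minimum of the two selectors", {
  expect_equal(final_threshold(100, 90), 90)
  expect_equal(final_threshold(80, 90), 80)
  expect_equal(final_threshold(90, 90), 90)
  with_seed(9, {
    for (i in 1:50) {
      a <- runif(1, 0, 255); b <- runif(1, 0, 255)
      expect_equal(final_threshold(a, b), min(a, b))
    }
  })
})

test_that("binarization partitions pixels at the threshold", {
  expect_equal(binarize(matrix(c(10, 200), 1, 2), 90, polarity = "low"),
               matrix(c(1L, 0L), 1, 2))
  expect_equal(binarize(matrix(c(10, 200), 1, 2), 90, polarity = "high"),
               matrix(c(0L, 1L), 1, 2))
  img <- rand_gray(55)
  expect_true(all(binarize(img, 255) == 0L))           # high polarity, T_f at max
  expect_true(all(binarize(img, -1) == 1L))
  m <- binarize(img, 128)
  expect_equal(sum(m == 1L) + sum(m == 0L), length(img))
  # the two polarities are exact complements
  expect_equal(m + binarize(img, 128, polarity = "low"), matrix(1L, 16, 16))
})

test_that("the threshold report combines both selectors and serializes", {
  img <- rand_gray(66)
  rep <- threshold_report(img)
  expect_s3_class(rep, "threshold_report")
  expect_equal(rep$T_f, min(rep$T_m, rep$T_n))
  expect_true(rep$T_m >= rep$T_min && rep$T_m <= rep$T_max)
  expect_gt(length(rep$iterations), 0L)
  j <- jsonlite::fromJSON(threshold_report_json(rep))
  expect_equal(j$T_f, rep$T_f)
  expect_equal(length(j$iterations), length(rep$iterations))
})

test_that("gray quantization maps the unit interval onto 0..255", {
  g <- gray_quantize(matrix(c(0, 0.5, 1), 1, 3))
  expect_identical(g, matrix(c(0L, 128L, 255L), 1, 3))
  expect_error(gray_quantize(matrix(1.5, 1, 1)), "normalized")
})
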