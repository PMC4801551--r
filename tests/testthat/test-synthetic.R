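small_cfg <- function(...) {
  scene_config(width = 120L, height = 90L, fruit_radius_range = c(12, 18), ...)
}

test_that("a scene is byte-identical under the same seed and differs across seeds", {
  s1 <- generate_scene(small_cfg(seed = 5))
  s2 <- generate_scene(small_cfg(seed = 5))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mature_masks, s2$mature_masks)
  s3 <- generate_scene(small_cfg(seed = 6))
  expect_false(identical(s1$image, s3$image))
})

test_that("ground truth is consistent: in-frame masks, positive areas, valid pixels", {
  sc <- generate_scene(small_cfg(seed = 11, n_immature = 2L, overlap_fraction = 0.4))
  expect_true(all(sc$image >= 0L & sc$image <= 255L))
  for (m in c(sc$mature_masks, sc$immature_masks)) {
    expect_equal(dim(m), dim(sc$image)[1:2])
    expect_gte(sum(m), 1L)
  }
  expect_equal(nrow(sc$fruit_geometry), 3L)
})

test_that("an unoccluded ripe fruit's mask is the rasterized disc", {
  sc <- generate_scene(small_cfg(seed = 21, n_immature = 0L, noise_sigma = 0))
  g <- sc$fruit_geometry[sc$fruit_geometry$type == "mature", ]
  area <- sum(sc$mature_masks[[1]])
  # direct pixel count of the disc from its stored center and radius
  rr <- matrix(seq_len(90), 90, 120)
  cc <- matrix(seq_len(120), 90, 120, byrow = TRUE)
  disc <- (rr - g$cy)^2 + (cc - g$cx)^2 <= g$r^2
  expect_equal(area, sum(disc))
  expect_lt(abs(area - pi * g$r^2), 4 * g$r)   # rasterization slack ~ perimeter
})

test_that("zero overlap keeps ripe and immature masks disjoint", {
  sc <- generate_scene(small_cfg(seed = 31, n_immature = 2L, overlap_fraction = 0))
  all_mature <- Reduce(`|`, sc$mature_masks)
  all_imm <- Reduce(`|`, sc$immature_masks)
  expect_equal(sum(all_mature & all_imm), 0L)
})

test_that("ripe-fruit pixels carry a higher mean a* than green pixels in every scene", {
  scenes <- c(generate_batch(3, "none", base_cfg = small_cfg(), seed = 50),
              generate_batch(3, "illumination", base_cfg = small_cfg(), seed = 60),
              generate_batch(3, "overlap", base_cfg = small_cfg(), seed = 70))
  for (sc in scenes) {
    a <- extract_feature_images(sc$image)$a_star$values
    mat <- Reduce(`|`, sc$mature_masks)
    other <- !mat
    expect_gt(mean(a[mat]), mean(a[other]))
    if (length(sc$immature_masks) > 0) {
      imm <- Reduce(`|`, sc$immature_masks)
      expect_gt(mean(a[mat]), mean(a[imm]))
    }
  }
})

test_that("batches derive per-scene seeds and apply the group presets", {
  b <- generate_batch(4, "illumination", base_cfg = small_cfg(), seed = 80)
  expect_length(b, 4L)
  for (sc in b) {
    expect_equal(sc$config$overlap_fraction, 0)
    expect_gt(sc$config$illumination_gradient_strength, 0.5)
    expect_equal(sc$disturbance, "illumination")
  }
  hashes <- vapply(b, function(s) paste(s$image[1:100], collapse = ","), "")
  expect_equal(length(unique(hashes)), 4L)

  b1 <- generate_batch(1, "overlap", base_cfg = small_cfg(), seed = 91)
  cfg <- unclass(small_cfg(seed = 91))
  cfg$overlap_fraction <- 0.6; cfg$n_immature <- 2L
  cfg$illumination_gradient_strength <- 0; cfg$highlight_probability <- 0
  direct <- generate_scene(do.call(scene_config, cfg), disturbance = "overlap")
  expect_identical(b1[[1]]$image, direct$image)
})

test_that("configurations are validated", {
  expect_error(scene_config(fruit_radius_range = c(200, 300)), "larger than image")
  expect_error(scene_config(overlap_fraction = 1.2), "\\[0, 1\\]")
  expect_error(scene_config(noise_sigma = -1), ">= 0")
})
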