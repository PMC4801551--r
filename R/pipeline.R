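#' Recognition pipeline configuration
#'
#' Defaults reproduce the method's standard settings: 3-level db2 wavelet
#' fusion, threshold tolerance 0.5 with bright-side foreground, 200-pixel
#' area filter with 8-connectivity. Unknown keys are rejected.
#'
#' @param method One of `"fusion"` (full pipeline), `"a_star_only"`,
#'   `"i_only"` (single-feature contrast arms), `"simple_fusion"`
#'   (pixel-average baseline).
#' @param fusion List: `levels`, `wavelet`, `boundary`,
#'   `per_subband_weight`.
#' @param threshold List: `tolerance`, `polarity`.
#' @param postprocess List: `min_area`, `connectivity`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("fusion", "a_star_only", "i_only", "simple_fusion"),
                            fusion = list(), threshold = list(), postprocess = list()) {
  method <- match.arg(method)
  merge_keys <- function(given, defaults, where) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown %s config key(s): %s", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    method = method,
    fusion = merge_keys(fusion,
                        list(levels = 3L, wavelet = "db2",
                             boundary = "periodization", per_subband_weight = FALSE),
                        "fusion"),
    threshold = merge_keys(threshold, list(tolerance = 0.5, polarity = "high"),
                           "threshold"),
    postprocess = merge_keys(postprocess, list(min_area = 200L, connectivity = 8L),
                             "postprocess")
  )
  stopifnot(cfg$fusion$levels >= 1L,
            cfg$threshold$polarity %in% c("high", "low"),
            cfg$postprocess$min_area >= 0,
            cfg$postprocess$connectivity %in% c(4L, 8L))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may contain top-level keys `method`, `fusion`, `threshold`,
#' `postprocess`, mirroring [pipeline_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), c("method", "fusion", "threshold", "postprocess"))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, y)
}

#' Segment ripe fruit in one RGB image
#'
#' Runs the three-layer recognition pipeline: (transformation) extract the
#' a* and I chromatic feature images and min-max normalize them;
#' (fusion) combine them by wavelet fusion — or use a single feature /
#' the simple average, per `method`; (extraction) quantize to 8-bit,
#' compute the iterative and Otsu thresholds, binarize at their minimum,
#' label connected components and remove regions below the area cutoff.
#'
#' @param img An H x W x 3 RGB array in 0..255, a `fruit_scene`, or an
#'   image file path.
#' @param config A [pipeline_config()].
#' @param keep_intermediates If `TRUE`, the feature and fused images are
#'   kept on the result (memory-heavy for batches; default `FALSE`).
#' @return An object of class `fruit_segmentation`: `mask` (0/1 matrix
#'   after area filtering), `regions` (`labeled_regions` of the surviving
#'   fruit candidates), `report` ([threshold_report()]), `method`,
#'   `fusion_weight` (for the fusion method), `config`, and optionally
#'   `intermediates`.
#' @export
segment_scene <- function(img, config = pipeline_config(), keep_intermediates = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  arr <- as_rgb_array(img)
  feats <- extract_feature_images(arr)
  a <- normalize_feature(feats$a_star)
  i <- normalize_feature(feats$I)
  fw <- NULL
  fused <- switch(config$method,
    fusion = {
      f <- fuse_images(a, i, levels = config$fusion$levels,
                       wavelet = config$fusion$wavelet,
                       boundary = config$fusion$boundary,
                       per_subband_weight = config$fusion$per_subband_weight)
      fw <- attr(f, "fusion_weight")
      f
    },
    a_star_only = a,
    i_only = i,
    simple_fusion = simple_fusion_baseline(a, i)
  )
  gray <- gray_quantize(fused$normalized)
  rep <- threshold_report(gray, tolerance = config$threshold$tolerance)
  mask <- binarize(gray, rep$T_f, polarity = config$threshold$polarity)
  lr <- label_regions(mask, connectivity = config$postprocess$connectivity)
  filt <- area_filter(lr, min_area = config$postprocess$min_area)
  out <- list(mask = filt$mask, regions = filt$regions, report = rep,
              method = config$method, fusion_weight = fw, config = config)
  if (keep_intermediates) {
    out$intermediates <- list(a_star = a, I = i, fused = fused, gray = gray,
                              raw_mask = mask)
  }
  structure(out, class = "fruit_segmentation")
}

#' @export
print.fruit_segmentation <- function(x, ...) {
  cat(sprintf("<fruit_segmentation> method=%s: %d region(s), %d foreground px\n",
              x$method, nrow(x$regions$regions), sum(x$mask)))
  print(x$report)
  if (!is.null(x$fusion_weight)) print(x$fusion_weight)
  invisible(x)
}

#' @export
summary.fruit_segmentation <- function(object, ...) {
  cat(sprintf("Fruit segmentation (%s method)\n", object$method))
  cat(sprintf("  thresholds: iterative %.2f, Otsu %.0f, final %.2f (%d iteration steps)\n",
              object$report$T_m, object$report$T_n, object$report$T_f,
              length(object$report$iterations)))
  cat(sprintf("  surviving regions (area >= %d px, %d-connectivity): %d\n",
              object$config$postprocess$min_area,
              object$config$postprocess$connectivity,
              nrow(object$regions$regions)))
  if (nrow(object$regions$regions) > 0L) print(object$regions$regions)
  invisible(object)
}

#' @export
plot.fruit_segmentation <- function(x, ...) {
  graphics::image(t(x$mask)[, nrow(x$mask):1], col = c("black", "red"),
                  axes = FALSE, asp = nrow(x$mask) / ncol(x$mask), ...)
  invisible(x)
}

#' Intersection-over-union of two masks
#' @param a,b Logical or 0/1 matrices of the same shape.
#' @return IoU in \[0, 1\] (0 when both are empty).
#' @export
mask_iou <- function(a, b) {
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

## Score one segmentation against one scene's ground truth.
## recognized: some surviving region matches a ripe-fruit mask with
## IoU >= iou_min, and no surviving region's best-matching truth mask is an
## immature fruit (false-positive guard: misidentified unripe fruit voids
## the image).
.score_one <- function(seg, truth, iou_min) {
  lab <- seg$regions$label_map
  k <- nrow(seg$regions$regions)
  best_iou <- 0
  false_pos <- FALSE
  if (k > 0L) {
    for (ri in seq_len(k)) {
      rmask <- lab == ri
      iou_mat <- vapply(truth$mature_masks, function(m) mask_iou(rmask, m), numeric(1L))
      iou_imm <- vapply(truth$immature_masks, function(m) mask_iou(rmask, m), numeric(1L))
      bm <- if (length(iou_mat) > 0L) max(iou_mat) else 0
      bi <- if (length(iou_imm) > 0L) max(iou_imm) else 0
      best_iou <- max(best_iou, bm)
      if (bi > bm && bi > 0) false_pos <- TRUE
    }
  }
  list(best_iou = best_iou,
       recognized = best_iou >= iou_min && !false_pos,
       false_positive = false_pos)
}

#' Evaluate segmentations against ground truth
#'
#' An image counts as recognized when some surviving region overlaps a
#' ripe-fruit truth mask with IoU at or above `iou_min` and no surviving
#' region matches an immature-fruit mask best (a misidentified unripe
#' fruit voids the image).
#'
#' @param results List of `fruit_segmentation` objects.
#' @param truths List of `fruit_scene` objects, aligned with `results`.
#' @param iou_min Recognition IoU cutoff (default 0.5).
#' @return An object of class `fruit_eval`: `per_image` data frame
#'   (`recognized`, `best_iou`, `false_positive`), `recognition_rate`,
#'   `iou_min`, `group`.
#' @export
evaluate <- function(results, truths, iou_min = 0.5) {
  if (length(results) != length(truths)) {
    stop("results and truths must have the same length", call. = FALSE)
  }
  scores <- Map(function(s, t) .score_one(s, t, iou_min), results, truths)
  per <- data.frame(
    recognized = vapply(scores, `[[`, logical(1L), "recognized"),
    best_iou = vapply(scores, `[[`, numeric(1L), "best_iou"),
    false_positive = vapply(scores, `[[`, logical(1L), "false_positive")
  )
  group <- unique(vapply(truths, `[[`, character(1L), "disturbance"))
  structure(list(per_image = per,
                 recognition_rate = mean(per$recognized),
                 iou_min = iou_min,
                 group = if (length(group) == 1L) group else "mixed"),
            class = "fruit_eval")
}

#' Segment and evaluate a batch of scenes, streaming
#'
#' Equivalent to running [segment_scene()] on every scene and then
#' [evaluate()], but without retaining the segmentations — suitable for
#' large batches.
#'
#' @param scenes List of `fruit_scene` objects.
#' @param config A [pipeline_config()].
#' @param iou_min Recognition IoU cutoff.
#' @return A `fruit_eval` object.
#' @export
evaluate_batch <- function(scenes, config = pipeline_config(), iou_min = 0.5) {
  scores <- lapply(scenes, function(sc) {
    .score_one(segment_scene(sc, config), sc, iou_min)
  })
  per <- data.frame(
    recognized = vapply(scores, `[[`, logical(1L), "recognized"),
    best_iou = vapply(scores, `[[`, numeric(1L), "best_iou"),
    false_positive = vapply(scores, `[[`, logical(1L), "false_positive")
  )
  group <- unique(vapply(scenes, `[[`, character(1L), "disturbance"))
  structure(list(per_image = per, recognition_rate = mean(per$recognized),
                 iou_min = iou_min,
                 group = if (length(group) == 1L) group else "mixed"),
            class = "fruit_eval")
}

#' @export
print.fruit_eval <- function(x, ...) {
  cat(sprintf("<fruit_eval> group=%s: %d/%d recognized (rate %.3f, IoU >= %.2f)\n",
              x$group, sum(x$per_image$recognized), nrow(x$per_image),
              x$recognition_rate, x$iou_min))
  invisible(x)
}

#' Contrast experiment across methods and disturbance groups
#'
#' Generates one scene batch per disturbance group, runs every requested
#' method on each batch and tabulates recognition rates — the standard
#' comparison of the fusion pipeline against its single-feature and
#' simple-average baselines under illumination and overlap disturbance.
#'
#' @param n_per_group Scenes per disturbance group.
#' @param seed Base seed (group g uses `seed + (g - 1) * n_per_group`).
#' @param config Base [pipeline_config()]; its `method` field is overridden
#'   per arm.
#' @param methods Methods to compare.
#' @param groups Disturbance groups to generate.
#' @param iou_min Recognition IoU cutoff.
#' @param base_cfg Base [scene_config()] for the generator.
#' @param verbose Log each cell as it completes.
#' @return Object of class `contrast_experiment`: `rates` (data frame,
#'   methods x groups), `n_per_group`, `seed`, `iou_min`.
#' @export
run_contrast_experiment <- function(n_per_group = 100L, seed = 1L,
                                    config = pipeline_config(),
                                    methods = c("fusion", "a_star_only",
                                                "i_only", "simple_fusion"),
                                    groups = c("illumination", "overlap"),
                                    iou_min = 0.5,
                                    base_cfg = scene_config(),
                                    verbose = TRUE) {
  rates <- matrix(NA_real_, length(methods), length(groups),
                  dimnames = list(methods, groups))
  for (gi in seq_along(groups)) {
    scenes <- generate_batch(n_per_group, groups[gi], base_cfg = base_cfg,
                             seed = seed + (gi - 1L) * n_per_group)
    for (mi in seq_along(methods)) {
      cfg <- config
      cfg$method <- methods[mi]
      ev <- evaluate_batch(scenes, cfg, iou_min = iou_min)
      rates[mi, gi] <- ev$recognition_rate
      if (verbose) {
        message(sprintf("[experiment] %-13s x %-12s rate = %.3f",
                        methods[mi], groups[gi], ev$recognition_rate))
      }
    }
    rm(scenes)
  }
  structure(list(rates = as.data.frame(rates), n_per_group = n_per_group,
                 seed = seed, iou_min = iou_min),
            class = "contrast_experiment")
}

#' @export
print.contrast_experiment <- function(x, ...) {
  cat(sprintf("<contrast_experiment> n = %d per group, seed = %d, IoU >= %.2f\n",
              x$n_per_group, x$seed, x$iou_min))
  print(round(x$rates, 3))
  invisible(x)
}
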