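## Synthetic tomato-canopy scenes with ground truth.
##
## The generator emulates greenhouse scenes from a low-resolution RGB
## camera: a dark-green foliage background textured with elliptical
## leaves/stems, one or more ripe (red, radially shaded) tomatoes, optional
## immature (light yellow-green) tomatoes that may occlude a ripe one, a
## multiplicative horizontal illumination gradient with optional specular
## highlights, and additive Gaussian pixel noise. Every scene is fully
## determined by its configuration, including the seed.

#' Run code with a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Synthetic scene configuration
#'
#' Defaults render a 388 x 260 scene (the target camera's resolution) with
#' one ripe tomato, two immature tomatoes and moderate foliage. Disturbance
#' knobs default to zero; [generate_batch()] raises them per disturbance
#' group.
#'
#' @param width,height Scene size in pixels.
#' @param n_mature,n_immature Numbers of ripe and unripe tomatoes.
#' @param fruit_radius_range Min/max fruit radius in pixels.
#' @param overlap_fraction In \[0, 1\]: fraction of a ripe fruit's boundary
#'   covered by each attached immature fruit (0 = disjoint; geometrically
#'   capped by the radius ratio).
#' @param illumination_gradient_strength In \[0, 1\]: strength of the
#'   multiplicative left-to-right illumination ramp (0 = flat lighting).
#' @param highlight_probability In \[0, 1\]: per-fruit probability of a
#'   small saturated specular highlight.
#' @param foliage_density In \[0, 1\]: scales the number of leaf/stem
#'   ellipses (about 60 at density 1).
#' @param noise_sigma Additive Gaussian noise s.d. in 8-bit gray units.
#' @param seed RNG seed; together with the other fields it fully determines
#'   the scene.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(width = 388L, height = 260L,
                         n_mature = 1L, n_immature = 2L,
                         fruit_radius_range = c(24, 40),
                         overlap_fraction = 0,
                         illumination_gradient_strength = 0,
                         highlight_probability = 0,
                         foliage_density = 0.5,
                         noise_sigma = 2,
                         seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_mature = as.integer(n_mature), n_immature = as.integer(n_immature),
              fruit_radius_range = as.numeric(fruit_radius_range),
              overlap_fraction = overlap_fraction,
              illumination_gradient_strength = illumination_gradient_strength,
              highlight_probability = highlight_probability,
              foliage_density = foliage_density,
              noise_sigma = noise_sigma, seed = as.integer(seed))
  stopifnot(cfg$width >= 16L, cfg$height >= 16L,
            cfg$n_mature >= 0L, cfg$n_immature >= 0L,
            length(cfg$fruit_radius_range) == 2L,
            cfg$fruit_radius_range[1L] > 0,
            cfg$fruit_radius_range[1L] <= cfg$fruit_radius_range[2L])
  for (f in c("overlap_fraction", "illumination_gradient_strength",
              "highlight_probability", "foliage_density")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(sprintf("%s must be in [0, 1]", f), call. = FALSE)
  }
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (2 * cfg$fruit_radius_range[2L] + 10 > min(cfg$width, cfg$height)) {
    stop("fruit larger than image: reduce fruit_radius_range or enlarge the scene",
         call. = FALSE)
  }
  structure(cfg, class = "scene_config")
}

## Paint a (possibly rotated) ellipse onto the canvas, restricted to its
## bounding box. canvas: H x W x 3; col3: RGB triple; shade: optional
## spherical shading. Returns list(canvas, mask_idx) where mask_idx are
## linear H x W indices of the painted pixels.
.paint_ellipse <- function(canvas, cy, cx, ay, ax, theta, col3, shade = FALSE) {
  h <- dim(canvas)[1L]; w <- dim(canvas)[2L]
  ext <- max(ay, ax)
  r0 <- max(1L, floor(cy - ext)); r1 <- min(h, ceiling(cy + ext))
  c0 <- max(1L, floor(cx - ext)); c1 <- min(w, ceiling(cx + ext))
  if (r0 > r1 || c0 > c1) return(list(canvas = canvas, mask_idx = integer()))
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  dy <- rr - cy; dx <- cc - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  q <- (u / ax)^2 + (v / ay)^2
  inside <- q <= 1
  if (!any(inside)) return(list(canvas = canvas, mask_idx = integer()))
  sub_idx <- which(inside)
  lin <- (as.vector(cc)[sub_idx] - 1L) * h + as.vector(rr)[sub_idx]
  fac <- if (shade) 0.7 + 0.3 * sqrt(pmax(0, 1 - q[inside])) else rep(1, length(sub_idx))
  npx <- h * w
  for (ch in 1:3) {
    canvas[lin + (ch - 1L) * npx] <- col3[ch] * fac
  }
  list(canvas = canvas, mask_idx = lin)
}

.disc_mask_idx <- function(h, w, cy, cx, r) {
  r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  inside <- (rr - cy)^2 + (cc - cx)^2 <= r^2
  (as.vector(cc)[which(inside)] - 1L) * h + as.vector(rr)[which(inside)]
}

#' Generate one synthetic canopy scene with ground truth
#'
#' See [scene_config()] for the knobs. Rendering order: background texture,
#' ripe fruit, immature fruit (drawn on top, so they occlude ripe fruit
#' where placed over them), illumination gradient, specular highlights,
#' Gaussian noise, clip to \[0, 255\] and round. Ground-truth masks are
#' modal (visible-surface): a ripe fruit's mask excludes pixels occluded by
#' an immature fruit drawn on top; immature masks are full discs.
#'
#' @param cfg A [scene_config()].
#' @param disturbance Tag stored on the scene: `"none"`, `"illumination"`
#'   or `"overlap"`.
#' @return An object of class `fruit_scene`: `image` (H x W x 3 integer
#'   array), `mature_masks` and `immature_masks` (lists of logical H x W
#'   matrices), `fruit_geometry` (data frame of fruit centers and radii, or
#'   `NULL` when the scene has no fruit), `disturbance`, `config`.
#' @export
generate_scene <- function(cfg = scene_config(), disturbance = "none") {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width
    canvas <- array(0, c(h, w, 3L))
    ## base background: dark green with a mild vertical tone sweep
    base_g <- 60 + 20 * (seq_len(h) - 1) / max(1L, h - 1L)
    canvas[, , 1L] <- 0.55 * base_g
    canvas[, , 2L] <- base_g
    canvas[, , 3L] <- 0.55 * base_g

    ## foliage: leaves (fat ellipses) and stems (thin elongated ellipses)
    n_leaf <- round(cfg$foliage_density * 60)
    for (i in seq_len(n_leaf)) {
      g <- runif(1, 90, 150)
      col3 <- c(g * runif(1, 0.30, 0.55), g, g * runif(1, 0.30, 0.60))
      res <- .paint_ellipse(canvas, runif(1, 1, h), runif(1, 1, w),
                            runif(1, 5, 25), runif(1, 8, 35),
                            runif(1, 0, pi), col3)
      canvas <- res$canvas
    }
    n_stem <- round(cfg$foliage_density * 8)
    for (i in seq_len(n_stem)) {
      g <- runif(1, 80, 120)
      col3 <- c(g * runif(1, 0.55, 0.75), g, g * runif(1, 0.25, 0.45))
      res <- .paint_ellipse(canvas, runif(1, 1, h), runif(1, 1, w),
                            runif(1, 1.5, 3), runif(1, 30, 90),
                            runif(1, 0, pi), col3)
      canvas <- res$canvas
    }

    ## ripe fruit: red shaded discs, kept inside the frame and mutually disjoint
    mature <- list()
    margin <- function(r) r + 6
    for (i in seq_len(cfg$n_mature)) {
      for (try in 1:200) {
        r <- runif(1, cfg$fruit_radius_range[1L], cfg$fruit_radius_range[2L])
        cy <- runif(1, margin(r), h - margin(r))
        cx <- runif(1, margin(r), w - margin(r))
        ok <- all(vapply(mature, function(m) {
          sqrt((m$cy - cy)^2 + (m$cx - cx)^2) > m$r + r + 4
        }, logical(1L)))
        if (ok) break
      }
      mature[[i]] <- list(cy = cy, cx = cx, r = r,
                          col = c(runif(1, 170, 230), runif(1, 35, 85), runif(1, 30, 70)))
    }
    ## immature fruit: light yellow-green shaded discs; with overlap > 0 they
    ## are attached to a ripe fruit, otherwise placed clear of all ripe fruit
    immature <- list()
    for (i in seq_len(cfg$n_immature)) {
      r <- runif(1, cfg$fruit_radius_range[1L], cfg$fruit_radius_range[2L])
      if (cfg$overlap_fraction > 0 && length(mature) > 0L) {
        ## occluders in a cluster are drawn relative to the host so the ripe
        ## fruit stays partly visible (an unrecognizable sample teaches nothing)
        host0 <- mature[[1L + (i - 1L) %% length(mature)]]
        r <- runif(1, 0.55, 0.80) * host0$r
        ## place the immature disc so it covers overlap_fraction of the host
        ## fruit's boundary: the host arc inside a disc of radius r at center
        ## distance dd has half-angle acos((dd^2 + R^2 - r^2) / (2 dd R));
        ## invert for dd, capping at the largest arc this radius can cover
        host <- mature[[1L + (i - 1L) %% length(mature)]]
        ang <- runif(1, 0, 2 * pi)
        alpha <- pi * cfg$overlap_fraction
        ## largest arc a disc of radius r can cover sits at half-angle
        ## asin(r/R); stay just inside it so the occluder remains at the rim
        ## instead of sliding toward the host's center
        amax <- if (r >= host$r) pi / 2 else asin(r / host$r)
        alpha <- min(alpha, 0.95 * amax)
        dd <- host$r * cos(alpha) + sqrt(max(0, r^2 - (host$r * sin(alpha))^2))
        cy <- min(max(host$cy + dd * sin(ang), r + 1), h - r - 1)
        cx <- min(max(host$cx + dd * cos(ang), r + 1), w - r - 1)
      } else {
        for (try in 1:200) {
          cy <- runif(1, margin(r), h - margin(r))
          cx <- runif(1, margin(r), w - margin(r))
          clear <- all(vapply(mature, function(m) {
            sqrt((m$cy - cy)^2 + (m$cx - cx)^2) > m$r + r + 3
          }, logical(1L)))
          if (clear) break
        }
      }
      g <- runif(1, 150, 200)
      immature[[i]] <- list(cy = cy, cx = cx, r = r,
                            col = c(g * runif(1, 0.68, 0.85), g, runif(1, 45, 80)))
    }

    mature_masks <- vector("list", length(mature))
    for (i in seq_along(mature)) {
      m <- mature[[i]]
      res <- .paint_ellipse(canvas, m$cy, m$cx, m$r, m$r, 0, m$col, shade = TRUE)
      canvas <- res$canvas
      msk <- matrix(FALSE, h, w); msk[res$mask_idx] <- TRUE
      mature_masks[[i]] <- msk
    }
    immature_masks <- vector("list", length(immature))
    for (i in seq_along(immature)) {
      m <- immature[[i]]
      res <- .paint_ellipse(canvas, m$cy, m$cx, m$r, m$r, 0, m$col, shade = TRUE)
      canvas <- res$canvas
      msk <- matrix(FALSE, h, w); msk[res$mask_idx] <- TRUE
      immature_masks[[i]] <- msk
      ## ripe-fruit truth masks are modal (visible surface): occluded pixels
      ## belong to the fruit drawn on top
      for (j in seq_along(mature_masks)) {
        mature_masks[[j]][res$mask_idx] <- FALSE
      }
    }

    ## multiplicative left-to-right illumination ramp
    s <- cfg$illumination_gradient_strength
    if (s > 0) {
      gain <- (1 - 0.6 * s) + (1.5 * s) * (seq_len(w) - 1) / max(1L, w - 1L)
      for (ch in 1:3) canvas[, , ch] <- sweep(canvas[, , ch], 2L, gain, `*`)
    }
    ## specular highlights: small saturated discs near the upper-left of a fruit
    if (cfg$highlight_probability > 0) {
      for (m in c(mature, immature)) {
        if (runif(1) < cfg$highlight_probability) {
          hi <- .disc_mask_idx(h, w, m$cy - 0.35 * m$r, m$cx - 0.35 * m$r,
                               max(2, 0.3 * m$r))
          npx <- h * w
          for (ch in 1:3) canvas[hi + (ch - 1L) * npx] <- 252
        }
      }
    }
    if (cfg$noise_sigma > 0) {
      canvas <- canvas + array(stats::rnorm(length(canvas), 0, cfg$noise_sigma),
                               dim(canvas))
    }
    canvas <- round(pmin(pmax(canvas, 0), 255))
    storage.mode(canvas) <- "integer"
    geom <- do.call(rbind, c(
      lapply(mature, function(m) data.frame(type = "mature", cy = m$cy, cx = m$cx, r = m$r)),
      lapply(immature, function(m) data.frame(type = "immature", cy = m$cy, cx = m$cx, r = m$r))
    ))
    structure(list(image = canvas, mature_masks = mature_masks,
                   immature_masks = immature_masks,
                   fruit_geometry = geom,
                   disturbance = disturbance, config = cfg),
              class = "fruit_scene")
  })
}

#' @export
print.fruit_scene <- function(x, ...) {
  cat(sprintf("<fruit_scene> %d x %d, %d ripe + %d immature fruit, disturbance=%s, seed=%d\n",
              nrow(x$image), ncol(x$image), length(x$mature_masks),
              length(x$immature_masks), x$disturbance, x$config$seed))
  invisible(x)
}

#' @export
plot.fruit_scene <- function(x, ...) {
  graphics::plot(c(0, ncol(x$image)), c(0, nrow(x$image)), type = "n", asp = 1,
                 xlab = "", ylab = "", axes = FALSE, ...)
  graphics::rasterImage(x$image / 255, 0, 0, ncol(x$image), nrow(x$image))
  invisible(x)
}

#' Generate a batch of scenes for one disturbance group
#'
#' Scene `i` uses seed `seed + i - 1`. Group presets (applied on top of
#' `base_cfg`): the illumination group sets a strong gradient
#' (strength 0.7) with frequent highlights (probability 0.9) and no
#' overlap; the overlap group sets deep overlap (fraction 0.6, two immature
#' fruit) with flat lighting; the none group zeroes every disturbance and
#' drops the immature fruit.
#'
#' @param n Number of scenes.
#' @param disturbance `"none"`, `"illumination"` or `"overlap"`.
#' @param base_cfg Base [scene_config()]; disturbance knobs are overridden
#'   by the group preset.
#' @param seed Base seed for the batch.
#' @return List of `fruit_scene` objects.
#' @export
generate_batch <- function(n, disturbance = c("none", "illumination", "overlap"),
                           base_cfg = scene_config(), seed = 1L) {
  disturbance <- match.arg(disturbance)
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    cfg <- unclass(base_cfg)
    cfg$seed <- as.integer(seed + i - 1L)
    if (disturbance == "illumination") {
      cfg$illumination_gradient_strength <- 0.7
      cfg$highlight_probability <- 0.9
      cfg$overlap_fraction <- 0
    } else if (disturbance == "overlap") {
      cfg$overlap_fraction <- 0.6
      cfg$n_immature <- max(2L, cfg$n_immature)
      cfg$illumination_gradient_strength <- 0
      cfg$highlight_probability <- 0
    } else {
      cfg$overlap_fraction <- 0
      cfg$illumination_gradient_strength <- 0
      cfg$highlight_probability <- 0
      cfg$n_immature <- 0L
    }
    generate_scene(do.call(scene_config, cfg), disturbance = disturbance)
  })
}
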