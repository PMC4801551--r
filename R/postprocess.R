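#' Connected-component labeling of a binary mask
#'
#' Labels connected foreground regions with consecutive positive integers
#' (0 = background) and tabulates per-region area, bounding box and
#' centroid. 4-connected labeling is done by `EBImage::bwlabel`;
#' 8-connectivity (the default — fruit blobs are compact and 8-connectivity
#' avoids splitting anti-aliased boundaries) additionally merges 4-connected
#' labels that touch diagonally.
#'
#' @param mask Integer/logical matrix; non-zero is foreground.
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `labeled_regions`: `label_map` (integer
#'   matrix), `regions` (data frame with columns `label`, `area`,
#'   `row_min`, `row_max`, `col_min`, `col_max`, `centroid_row`,
#'   `centroid_col`), `connectivity`.
#' @export
label_regions <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  fg <- mask != 0
  lab <- matrix(as.integer(EBImage::bwlabel(fg)), nrow(fg), ncol(fg))
  if (connectivity == 8L && max(lab) > 1L) {
    lab <- .merge_diagonal(lab)
  }
  ## relabel consecutively in first-occurrence (column-major) order
  u <- unique(lab[lab > 0L])
  if (length(u) > 0L) {
    remap <- integer(max(u))
    remap[u] <- seq_along(u)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  structure(list(label_map = lab, regions = .region_table(lab),
                 connectivity = as.integer(connectivity)),
            class = "labeled_regions")
}

## Union labels of 4-connected components that touch diagonally.
.merge_diagonal <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1L, -1L]   # down-right neighbors
  c_ <- lab[-nr, -1L]; d <- lab[-1L, -nc]  # down-left neighbors
  pairs <- rbind(
    cbind(as.vector(a), as.vector(b)),
    cbind(as.vector(c_), as.vector(d))
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L & pairs[, 1L] != pairs[, 2L], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  k <- max(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs[r, 1L]); rj <- find(pairs[r, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(k), find, integer(1L))
  pos <- lab > 0L
  lab[pos] <- root[lab[pos]]
  lab
}

.region_table <- function(lab) {
  k <- max(lab)
  if (k == 0L) {
    return(data.frame(label = integer(), area = integer(),
                      row_min = integer(), row_max = integer(),
                      col_min = integer(), col_max = integer(),
                      centroid_row = numeric(), centroid_col = numeric()))
  }
  idx <- which(lab > 0L)
  l <- factor(lab[idx], levels = seq_len(k))
  r <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(l, nbins = k)
  data.frame(
    label = seq_len(k),
    area = area,
    row_min = as.integer(tapply(r, l, min)),
    row_max = as.integer(tapply(r, l, max)),
    col_min = as.integer(tapply(cc, l, min)),
    col_max = as.integer(tapply(cc, l, max)),
    centroid_row = as.numeric(tapply(r, l, mean)),
    centroid_col = as.numeric(tapply(cc, l, mean)),
    row.names = NULL
  )
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d region(s), connectivity %d, %d foreground px\n",
              nrow(x$regions), x$connectivity, sum(x$label_map > 0L)))
  if (nrow(x$regions) > 0L) print(utils::head(x$regions, 10L))
  invisible(x)
}

#' Remove small regions from a labeled mask
#'
#' Area-based noise removal: connected regions whose pixel area is below
#' `min_area` are deleted; regions of exactly `min_area` pixels are kept.
#' The default of 200 pixels is the pipeline's standard noise cutoff.
#'
#' @param lr A `labeled_regions` object (or a binary mask, which is labeled
#'   first with 8-connectivity).
#' @param min_area Minimum surviving region area in pixels (default 200).
#' @return A list with `mask` (filtered 0/1 integer matrix) and `regions`
#'   (the filtered, relabeled `labeled_regions`).
#' @export
area_filter <- function(lr, min_area = 200L) {
  if (is.matrix(lr)) lr <- label_regions(lr)
  stopifnot(inherits(lr, "labeled_regions"), min_area >= 0)
  keep <- lr$regions$label[lr$regions$area >= min_area]
  lab <- lr$label_map
  lab[!(lab %in% keep)] <- 0L
  if (length(keep) > 0L) {
    remap <- integer(max(keep))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  reg <- lr$regions[lr$regions$area >= min_area, , drop = FALSE]
  reg$label <- seq_len(nrow(reg))
  row.names(reg) <- NULL
  out_lr <- structure(list(label_map = lab, regions = reg,
                           connectivity = lr$connectivity),
                      class = "labeled_regions")
  list(mask = matrix(as.integer(lab > 0L), nrow(lab), ncol(lab)),
       regions = out_lr)
}
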