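# Spatial train/test split, random training-crop sampling, and edge-ignoring
# test tiling. Test tiles overlap by 2*margin; after prediction only each
# tile's central window is kept ("the edge regions are replaced with the
# middle regions of adjacent images"), with windows at the region border
# extended to the border, so retained windows partition the region exactly.

#' Tiling specification
#'
#' @param size tile side length in pixels (default 256).
#' @param margin ignored edge width m for test tiles; requires
#'   `size > 2 * margin > 0`.
#' @param count training crops per scene (default 800).
#' @param n_train,n_val partition of `count` into training and validation
#'   crops (defaults 600/200).
#' @param ratio train/test area split (default 0.6, i.e. 6:4).
#' @param axis `"col"` (vertical dividing line) or `"row"`.
#' @param seed integer seed for crop sampling.
#' @return object of class `tile_spec`.
#' @export
tile_spec <- function(size = 256L, margin = 32L, count = 800L,
                      n_train = 600L, n_val = 200L, ratio = 0.6,
                      axis = c("col", "row"), seed = 1L) {
  axis <- match.arg(axis)
  if (!(size > 2 * margin && margin > 0))
    stop("tile size must exceed 2 * margin and margin must be positive")
  if (n_train + n_val != count)
    stop("count must equal n_train + n_val")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  structure(list(size = as.integer(size), margin = as.integer(margin),
                 count = as.integer(count), n_train = as.integer(n_train),
                 n_val = as.integer(n_val), ratio = ratio, axis = axis,
                 seed = as.integer(seed)),
            class = "tile_spec")
}

region_new <- function(rows, cols) {
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "scene_region")
}

region_dims <- function(r) c(diff(r$rows) + 1L, diff(r$cols) + 1L)

#' Split a scene into rectangular train and test regions
#'
#' Divides the scene by a straight line perpendicular to `axis`, giving the
#' training region a `ratio` share of the area (to the nearest pixel line).
#'
#' @param scene_shape `c(rows, cols)` of the scene.
#' @param ratio training share in (0, 1); default 0.6 (a 6:4 split).
#' @param axis `"row"` splits along rows (training block on top), `"col"`
#'   along columns (training block on the left).
#' @return list with `scene_region` elements `train` and `test`.
#' @export
split_train_test <- function(scene_shape, ratio = 0.6, axis = c("col", "row")) {
  axis <- match.arg(axis)
  if (any(scene_shape[1:2] < 2L)) stop("degenerate scene shape")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n <- if (axis == "row") scene_shape[1] else scene_shape[2]
  cut <- round(ratio * n)
  if (cut < 1L || cut >= n) stop("split leaves an empty region")
  if (axis == "row") {
    list(train = region_new(c(1L, cut), c(1L, scene_shape[2])),
         test = region_new(c(cut + 1L, scene_shape[1]), c(1L, scene_shape[2])))
  } else {
    list(train = region_new(c(1L, scene_shape[1]), c(1L, cut)),
         test = region_new(c(1L, scene_shape[1]), c(cut + 1L, scene_shape[2])))
  }
}

crop_window <- function(arr, r0, c0, size) {
  if (length(dim(arr)) == 3L)
    arr[r0:(r0 + size - 1L), c0:(c0 + size - 1L), , drop = FALSE]
  else
    arr[r0:(r0 + size - 1L), c0:(c0 + size - 1L), drop = FALSE]
}

#' Randomly sample training/validation crops from a region
#'
#' Draws `spec$count` tile origins uniformly (tiles lie fully inside the
#' region; crops may overlap), pairing each feature crop with its label crop.
#' The first `n_train` crops are the training split, the rest validation.
#'
#' @param features rank-3 feature array (e.g. a normalized `feature_stack`).
#' @param labels a [label_raster()] or integer matrix aligned with `features`.
#' @param region a `scene_region` from [split_train_test()].
#' @param spec a [tile_spec()].
#' @return a `tile_set`: list of tiles (`x`, `y`, `origin`, `role`) plus the
#'   spec and region.
#' @export
sample_training_tiles <- function(features, labels, region, spec) {
  lab <- if (inherits(labels, "label_raster")) labels$values else labels
  stopifnot_aligned(features, lab)
  rd <- region_dims(region)
  if (any(rd < spec$size))
    stop("region (", paste(rd, collapse = "x"), ") smaller than tile size ",
         spec$size)
  set.seed(spec$seed)
  r0 <- sample.int(rd[1] - spec$size + 1L, spec$count, replace = TRUE) +
    region$rows[1] - 1L
  c0 <- sample.int(rd[2] - spec$size + 1L, spec$count, replace = TRUE) +
    region$cols[1] - 1L
  roles <- rep(c("train", "val"), c(spec$n_train, spec$n_val))
  tiles <- lapply(seq_len(spec$count), function(i) {
    list(x = crop_window(features, r0[i], c0[i], spec$size),
         y = crop_window(lab, r0[i], c0[i], spec$size),
         origin = c(r0[i], c0[i]), role = roles[i])
  })
  structure(list(tiles = tiles, spec = spec, region = region),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  roles <- table(vapply(x$tiles, `[[`, "", "role"))
  cat(sprintf("<tile_set> %d tiles of %d x %d (%s)\n", length(x$tiles),
              x$spec$size, x$spec$size,
              paste(names(roles), roles, sep = "=", collapse = ", ")))
  invisible(x)
}

# Tile origins and retained central windows along one axis (absolute coords).
# Origins advance by stride = size - 2m; the final tile is shifted inward so
# it ends exactly at the region border. Retained windows are [o+m, o+size-m-1]
# capped so adjacent windows abut, and extended to the region border at the
# two ends: they partition [start, end].
axis_layout <- function(start, end, size, m) {
  len <- end - start + 1L
  if (len < size) stop("region extent ", len, " smaller than tile size ", size)
  stride <- size - 2L * m
  origins <- integer(0)
  o <- start
  repeat {
    if (o + size - 1L >= end) {
      origins <- c(origins, end - size + 1L)
      break
    }
    origins <- c(origins, o)
    o <- o + stride
  }
  n <- length(origins)
  a <- origins + m
  b <- origins + size - m - 1L
  if (n > 1L)
    b[-n] <- pmin(b[-n], origins[-1L] + m - 1L)
  a[1] <- start
  b[n] <- end
  data.frame(origin = origins, keep_from = a, keep_to = b)
}

#' Lay out overlapping test tiles over a region
#'
#' Tiles are placed on a grid with stride `size - 2 * margin` so neighbours
#' overlap by `2 * margin`; border tiles are shifted inward so no tile leaves
#' the raster. Each tile records the central window it "owns"; the retained
#' windows partition the region with no gaps and no double assignment.
#'
#' @param features rank-3 feature array covering the scene.
#' @param region a `scene_region`.
#' @param spec a [tile_spec()]; uses `size` and `margin`.
#' @return a `tile_set` with role `"test"`; each tile carries `origin` and its
#'   retained window `keep` (absolute `rows`/`cols` ranges).
#' @export
tile_test_region <- function(features, region, spec) {
  rl <- axis_layout(region$rows[1], region$rows[2], spec$size, spec$margin)
  cl <- axis_layout(region$cols[1], region$cols[2], spec$size, spec$margin)
  tiles <- list()
  for (cj in seq_len(nrow(cl))) for (ri in seq_len(nrow(rl))) {
    tiles[[length(tiles) + 1L]] <- list(
      x = crop_window(features, rl$origin[ri], cl$origin[cj], spec$size),
      origin = c(rl$origin[ri], cl$origin[cj]),
      keep = list(rows = c(rl$keep_from[ri], rl$keep_to[ri]),
                  cols = c(cl$keep_from[cj], cl$keep_to[cj])),
      role = "test")
  }
  structure(list(tiles = tiles, spec = spec, region = region),
            class = "tile_set")
}

#' Stitch per-tile predictions back into a region-sized label raster
#'
#' Takes one predicted class matrix per test tile (same order as the
#' `tile_set`) and assembles the region's prediction from each tile's retained
#' central window, mirroring the edge-ignoring layout used at tiling time.
#'
#' @param pred_tiles list of integer matrices, `size x size`, one per tile.
#' @param tile_set the `tile_set` produced by [tile_test_region()].
#' @return integer matrix with the region's dimensions; every pixel assigned
#'   exactly once.
#' @export
stitch_predictions <- function(pred_tiles, tile_set) {
  stopifnot(inherits(tile_set, "tile_set"))
  if (length(pred_tiles) != length(tile_set$tiles))
    stop("expected ", length(tile_set$tiles), " predicted tiles, got ",
         length(pred_tiles))
  region <- tile_set$region
  rd <- region_dims(region)
  out <- matrix(NA_integer_, rd[1], rd[2])
  size <- tile_set$spec$size
  for (i in seq_along(pred_tiles)) {
    t <- tile_set$tiles[[i]]
    p <- pred_tiles[[i]]
    if (!all(dim(p)[1:2] == c(size, size)))
      stop("predicted tile ", i, " has wrong shape")
    kr <- t$keep$rows; kc <- t$keep$cols
    out[(kr[1]:kr[2]) - region$rows[1] + 1L,
        (kc[1]:kc[2]) - region$cols[1] + 1L] <-
      p[(kr[1]:kr[2]) - t$origin[1] + 1L, (kc[1]:kc[2]) - t$origin[2] + 1L]
  }
  if (anyNA(out)) stop("stitching left unassigned pixels (missing tile?)")
  out
}
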