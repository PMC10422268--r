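# Synthetic labeled multispectral mosaics. The generator states a simple world:
# axis-aligned rectangular plots, class-wise Gaussian spectral signatures with
# the vegetated classes (corn, soybean) separated mainly in the red-edge and
# near-infrared bands, mixed pixels at plot boundaries, and affine per-band
# shifts standing in for inter-annual spectral variation.

#' Class-wise spectral library
#'
#' Per-class mean reflectance over the six raw bands plus a band-wise noise
#' standard deviation. The default emulates mid-season crop spectra: both crops
#' dark in the visible, bright in the near-infrared, separated chiefly in the
#' red-edge (band 5/6) and NIR (band 8) region; "other" is a spectrally flat,
#' low-NIR background (bare soil / built-up).
#'
#' @param means numeric matrix, classes x bands, reflectance in `[0, 1]`; row
#'   names are class names, column names band names.
#' @param sds noise standard deviations, same shape (or a scalar recycled).
#' @return object of class `spectral_library`.
#' @export
spectral_library <- function(means = NULL, sds = 0.01) {
  if (is.null(means)) {
    means <- rbind(
      other   = c(0.10, 0.13, 0.16, 0.18, 0.20, 0.22),
      corn    = c(0.030, 0.070, 0.040, 0.120, 0.320, 0.420),
      soybean = c(0.030, 0.080, 0.045, 0.180, 0.400, 0.520))
    colnames(means) <- DEFAULT_BANDS
  }
  if (length(sds) == 1L) sds <- matrix(sds, nrow(means), ncol(means),
                                       dimnames = dimnames(means))
  stopifnot(all(dim(sds) == dim(means)))
  if (any(means < 0 | means > 1)) stop("spectral means must lie in [0, 1]")
  if (any(sds < 0)) stop("noise standard deviations must be >= 0")
  need <- names(DEFAULT_CLASSES)
  if (!all(need %in% rownames(means)))
    stop("library must cover classes: ", paste(need, collapse = ", "))
  structure(list(means = means, sds = sds, bands = colnames(means)),
            class = "spectral_library")
}

#' Mosaic geometry configuration
#'
#' @param height,width scene size in pixels; at least 256 each.
#' @param plot_size two-element range of plot side lengths in pixels.
#' @param priors named class prior probabilities; must sum to 1.
#' @param mix_width boundary-mixing half-width in pixels (0 disables mixing).
#' @param seed integer random seed; the generator is deterministic given it.
#' @return object of class `mosaic_config`.
#' @export
mosaic_config <- function(height = 768, width = 768, plot_size = c(40, 96),
                          priors = c(other = 0.2, corn = 0.4, soybean = 0.4),
                          mix_width = 1, seed = 1L) {
  if (height < 256 || width < 256)
    stop("scene must be at least 256 x 256 pixels")
  if (length(plot_size) != 2L || plot_size[1] < 2 || plot_size[2] < plot_size[1])
    stop("plot_size must be an increasing pair of side lengths >= 2")
  if (abs(sum(priors) - 1) > 1e-8) stop("class priors must sum to 1")
  if (any(priors < 0)) stop("class priors must be nonnegative")
  if (mix_width < 0) stop("mix_width must be >= 0")
  if (!all(names(priors) %in% names(DEFAULT_CLASSES)))
    stop("priors must be named with classes: ",
         paste(names(DEFAULT_CLASSES), collapse = ", "))
  structure(list(height = as.integer(height), width = as.integer(width),
                 plot_size = plot_size, priors = priors,
                 mix_width = as.integer(mix_width), seed = as.integer(seed)),
            class = "mosaic_config")
}

# Random 1-d partition with segment lengths ~ U[lo, hi]; a trailing remainder
# shorter than lo is merged into the final segment (which may then exceed hi
# by at most lo - 1).
partition_axis <- function(n, lo, hi) {
  cuts <- 0L
  while (tail(cuts, 1L) < n) {
    step <- floor(runif(1, lo, hi + 1))
    cuts <- c(cuts, min(tail(cuts, 1L) + step, n))
  }
  if (length(cuts) > 2L && diff(tail(cuts, 2L)) < lo)
    cuts <- cuts[-(length(cuts) - 1L)]
  cuts
}

#' Generate a rectangular field mosaic of class labels
#'
#' Partitions the scene into axis-aligned rectangular plots whose side lengths
#' are drawn uniformly from `plot_size`, then assigns each plot a class from
#' the priors. A plot that would repeat the class of its left or top neighbour
#' is resampled (twice) so that neighbouring plots usually differ, keeping
#' connected same-class components close to single-plot size; under degenerate
#' priors (a single class with probability 1) resampling has no effect.
#'
#' @param cfg a [mosaic_config()].
#' @return a [label_raster()] with the mosaic geometry attached as attributes
#'   `config` (the `cfg` used) for downstream rendering.
#' @export
generate_field_mosaic <- function(cfg) {
  stopifnot(inherits(cfg, "mosaic_config"))
  set.seed(cfg$seed)
  rcuts <- partition_axis(cfg$height, cfg$plot_size[1], cfg$plot_size[2])
  ccuts <- partition_axis(cfg$width, cfg$plot_size[1], cfg$plot_size[2])
  nr <- length(rcuts) - 1L
  nc <- length(ccuts) - 1L
  codes <- DEFAULT_CLASSES[names(cfg$priors)]
  cell <- matrix(NA_integer_, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    cl <- sample(codes, 1L, prob = cfg$priors)
    for (try in 1:2) {
      clash <- (i > 1L && cell[i - 1L, j] == cl) ||
               (j > 1L && cell[i, j - 1L] == cl)
      if (!clash) break
      cl <- sample(codes, 1L, prob = cfg$priors)
    }
    cell[i, j] <- cl
  }
  values <- matrix(NA_integer_, cfg$height, cfg$width)
  for (j in seq_len(nc)) for (i in seq_len(nr))
    values[(rcuts[i] + 1L):rcuts[i + 1L], (ccuts[j] + 1L):ccuts[j + 1L]] <-
      cell[i, j]
  out <- label_raster(values)
  attr(out, "config") <- cfg
  out
}

# TRUE for pixels within Chebyshev distance `width` of a class boundary
# (a pixel whose 4-neighbourhood contains a different class).
boundary_zone <- function(values, width) {
  H <- nrow(values); W <- ncol(values)
  b <- matrix(FALSE, H, W)
  b[-H, ] <- b[-H, ] | (values[-H, ] != values[-1, ])
  b[-1, ] <- b[-1, ] | (values[-1, ] != values[-H, ])
  b[, -W] <- b[, -W] | (values[, -W] != values[, -1])
  b[, -1] <- b[, -1] | (values[, -1] != values[, -W])
  if (width > 1L) {
    z <- b
    for (k in seq_len(width - 1L)) {
      g <- z
      g[-1, ] <- g[-1, ] | z[-H, ]
      g[-H, ] <- g[-H, ] | z[-1, ]
      g[, -1] <- g[, -1] | z[, -W]
      g[, -W] <- g[, -W] | z[, -1]
      z <- g
    }
    b <- z
  }
  b
}

# 3x3 box mean with edge-aware normalisation, per matrix.
box3_mean <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  cnt <- matrix(0, H + 2L, W + 2L)
  cnt[2:(H + 1L), 2:(W + 1L)] <- 1
  s <- matrix(0, H, W); n <- matrix(0, H, W)
  for (di in 0:2) for (dj in 0:2) {
    s <- s + pad[(1:H) + di, (1:W) + dj]
    n <- n + cnt[(1:H) + di, (1:W) + dj]
  }
  s / n
}

#' Render a label mosaic into a multispectral reflectance scene
#'
#' Each pixel's band vector is its class mean plus independent Gaussian noise;
#' pixels within `mix_width` of a class boundary are then replaced by the 3x3
#' box average of the noisy image (mixed pixels), and everything is clipped to
#' `[0, 1]`.
#'
#' @param labels a [label_raster()].
#' @param lib a [spectral_library()] covering every class present.
#' @param seed integer seed for the rendering noise.
#' @param mix_width boundary half-width in pixels; defaults to the generating
#'   [mosaic_config()] when `labels` carries one, else 1.
#' @return a [multispectral_scene()].
#' @export
render_reflectance <- function(labels, lib, seed = 1L, mix_width = NULL) {
  stopifnot(inherits(labels, "label_raster"), inherits(lib, "spectral_library"))
  if (is.null(mix_width)) {
    cfg <- attr(labels, "config")
    mix_width <- if (!is.null(cfg)) cfg$mix_width else 1L
  }
  present <- names(labels$classes)[labels$classes %in% unique(as.vector(labels$values))]
  missing <- setdiff(present, rownames(lib$means))
  if (length(missing))
    stop("classes present in labels but absent from library: ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  H <- nrow(labels$values); W <- ncol(labels$values)
  nb <- length(lib$bands)
  arr <- array(NA_real_, c(H, W, nb))
  # row of lib$means for each pixel
  code_to_row <- match(names(labels$classes), rownames(lib$means))
  row_idx <- code_to_row[match(as.vector(labels$values), unname(labels$classes))]
  for (b in seq_len(nb)) {
    mu <- lib$means[row_idx, b]
    s <- lib$sds[row_idx, b]
    arr[, , b] <- matrix(mu + rnorm(H * W) * s, H, W)
  }
  if (mix_width > 0L) {
    zone <- boundary_zone(labels$values, mix_width)
    for (b in seq_len(nb)) {
      sm <- box3_mean(arr[, , b])
      plane <- arr[, , b]
      plane[zone] <- sm[zone]
      arr[, , b] <- plane
    }
  }
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  multispectral_scene(arr, bands = lib$bands)
}

#' Per-band affine "year" shift
#'
#' Stands in for inter-annual spectral variation: band b becomes
#' `clip(gain_b * value + offset_b, 0, 1)`.
#'
#' @param gain per-band multiplicative gain (scalar recycled); must be > 0.
#' @param offset per-band additive offset in reflectance units (scalar
#'   recycled).
#' @param n_bands number of bands the shift applies to.
#' @return object of class `year_shift`.
#' @export
year_shift <- function(gain = 1, offset = 0, n_bands = 6L) {
  gain <- rep_len(gain, n_bands)
  offset <- rep_len(offset, n_bands)
  if (any(gain <= 0)) stop("gains must be positive")
  structure(list(gain = gain, offset = offset), class = "year_shift")
}

#' Apply a year shift to a scene
#'
#' @param scene a [multispectral_scene()].
#' @param shift a [year_shift()] with one gain/offset per band.
#' @return the shifted [multispectral_scene()]; labels (held elsewhere) are
#'   unaffected by construction.
#' @export
simulate_year_shift <- function(scene, shift) {
  stopifnot(inherits(scene, "multispectral_scene"), inherits(shift, "year_shift"))
  nb <- dim(scene)[3]
  if (length(shift$gain) != nb)
    stop("shift has ", length(shift$gain), " bands; scene has ", nb)
  arr <- scene$reflectance
  for (b in seq_len(nb))
    arr[, , b] <- pmin(pmax(shift$gain[b] * arr[, , b] + shift$offset[b], 0), 1)
  multispectral_scene(arr, bands = scene$bands, mask = scene$mask)
}

#' Generate a complete labeled scene in one call
#'
#' @param cfg a [mosaic_config()].
#' @param lib a [spectral_library()].
#' @param shift optional [year_shift()] applied after rendering.
#' @return list with elements `scene` and `labels`.
#' @export
simulate_scene <- function(cfg, lib = spectral_library(), shift = NULL) {
  labels <- generate_field_mosaic(cfg)
  scene <- render_reflectance(labels, lib, seed = cfg$seed + 1L)
  if (!is.null(shift)) scene <- simulate_year_shift(scene, shift)
  list(scene = scene, labels = labels)
}
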