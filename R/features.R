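# The network input is an 8-channel stack: the six raw bands plus two derived
# vegetation indices (NDVI from NIR/red, red-edge NDVI from the two red-edge
# bands; an EVI alternative is available). Indices use safe division: pixels
# with a zero denominator get value 0 and are flagged.

safe_ratio_index <- function(num, den) {
  zero <- den == 0
  out <- matrix(0, nrow(num), ncol(num))
  out[!zero] <- num[!zero] / den[!zero]
  attr(out, "flagged") <- zero
  out
}

#' Normalized Difference Vegetation Index
#'
#' `NDVI = (NIR - R) / (NIR + R)` with NIR = band 8 and R = band 4. Pixels
#' where `NIR + R = 0` get NDVI 0 and are flagged in the `"flagged"`
#' attribute so the network input stays finite.
#'
#' @param scene a [multispectral_scene()] containing bands 4 and 8.
#' @return numeric matrix in `[-1, 1]` with a logical `"flagged"` attribute.
#' @export
compute_ndvi <- function(scene) {
  nir <- scene_band(scene, "band8")
  red <- scene_band(scene, "band4")
  safe_ratio_index(nir - red, nir + red)
}

#' Red-edge NDVI
#'
#' The red-edge analogue of NDVI using the 740 nm and 705 nm red-edge bands:
#' `(band6 - band5) / (band6 + band5)`. Sensitive to chlorophyll differences
#' that separate crop types when broadband NDVI saturates.
#'
#' @param scene a [multispectral_scene()] containing bands 5 and 6.
#' @return numeric matrix in `[-1, 1]` with a logical `"flagged"` attribute.
#' @export
compute_rededge_index <- function(scene) {
  b6 <- scene_band(scene, "band6")
  b5 <- scene_band(scene, "band5")
  safe_ratio_index(b6 - b5, b6 + b5)
}

#' Enhanced Vegetation Index
#'
#' `EVI = 2.5 (NIR - R) / (NIR + 6 R - 7.5 B + 1)` with NIR = band 8,
#' R = band 4, B = band 2. Provided as an alternative eighth channel.
#'
#' @param scene a [multispectral_scene()] containing bands 2, 4 and 8.
#' @return numeric matrix with a logical `"flagged"` attribute marking
#'   zero-denominator pixels.
#' @export
compute_evi <- function(scene) {
  nir <- scene_band(scene, "band8")
  red <- scene_band(scene, "band4")
  blue <- scene_band(scene, "band2")
  safe_ratio_index(2.5 * (nir - red), nir + 6 * red - 7.5 * blue + 1)
}

#' Build the 8-channel feature stack
#'
#' Stacks the six raw bands in order (band2, band3, band4, band5, band6,
#' band8) followed by NDVI and a second index chosen by `index_choice`
#' (red-edge NDVI by default, EVI as an option).
#'
#' @param scene a [multispectral_scene()] with all six raw bands.
#' @param index_choice `"rededge"` or `"evi"` for the eighth channel.
#' @return a `feature_stack`: rank-3 array rows x cols x 8 with attributes
#'   `channels` (names) and `normalized` (`FALSE`).
#' @export
build_feature_stack <- function(scene, index_choice = c("rededge", "evi")) {
  index_choice <- match.arg(index_choice)
  stopifnot(inherits(scene, "multispectral_scene"))
  if (!all(DEFAULT_BANDS %in% scene$bands))
    stop("scene must contain all six raw bands: ",
         paste(DEFAULT_BANDS, collapse = ", "))
  d <- dim(scene)
  stack <- array(NA_real_, c(d[1], d[2], 8L))
  for (b in seq_along(DEFAULT_BANDS))
    stack[, , b] <- scene_band(scene, DEFAULT_BANDS[b])
  stack[, , 7L] <- compute_ndvi(scene)
  stack[, , 8L] <- switch(index_choice,
                          rededge = compute_rededge_index(scene),
                          evi = compute_evi(scene))
  structure(stack, class = "feature_stack",
            channels = c(DEFAULT_BANDS, "ndvi", index_choice),
            normalized = FALSE)
}

#' Per-channel z-score normalization
#'
#' Standardizes each of the 8 channels. When `stats` is supplied (from the
#' training region) those statistics are reused, so test data is scaled
#' exactly like the data the network was fitted on; otherwise statistics are
#' computed from `stack` itself and returned for reuse.
#'
#' @param stack a `feature_stack` from [build_feature_stack()].
#' @param stats optional list with numeric vectors `mean` and `sd` (length 8).
#' @return the normalized `feature_stack`; the statistics used are attached as
#'   attribute `"stats"`.
#' @export
normalize_stack <- function(stack, stats = NULL) {
  stopifnot(inherits(stack, "feature_stack"))
  nch <- dim(stack)[3]
  if (is.null(stats)) {
    mu <- apply(stack, 3, mean)
    s <- apply(stack, 3, sd)
    if (any(s == 0)) {
      warning("channel(s) with zero variance: unit divisor used")
      s[s == 0] <- 1
    }
    stats <- list(mean = mu, sd = s)
  } else {
    stopifnot(length(stats$mean) == nch, length(stats$sd) == nch)
  }
  out <- stack
  for (ch in seq_len(nch))
    out[, , ch] <- (stack[, , ch] - stats$mean[ch]) / stats$sd[ch]
  attr(out, "stats") <- stats
  attr(out, "normalized") <- TRUE
  out
}

#' Nearest/bilinear raster resampling utility
#'
#' Convenience for putting rasters on a common grid; the main pipeline assumes
#' inputs are already aligned.
#'
#' @param m numeric matrix.
#' @param out_dim target `c(rows, cols)`.
#' @param method `"nearest"` or `"bilinear"`.
#' @return resampled matrix.
#' @export
resample_raster <- function(m, out_dim, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  ho <- out_dim[1]; wo <- out_dim[2]
  # map output pixel centres into input pixel coordinates
  ri <- (seq_len(ho) - 0.5) * H / ho + 0.5
  ci <- (seq_len(wo) - 0.5) * W / wo + 0.5
  if (method == "nearest") {
    m[pmin(pmax(round(ri), 1), H), pmin(pmax(round(ci), 1), W)]
  } else {
    r0 <- pmin(pmax(floor(ri), 1), H); r1 <- pmin(r0 + 1, H)
    c0 <- pmin(pmax(floor(ci), 1), W); c1 <- pmin(c0 + 1, W)
    fr <- ri - r0; fc <- ci - c0
    fr[r1 == r0] <- 0; fc[c1 == c0] <- 0
    (1 - fr) %o% (1 - fc) * m[r0, c0] + (1 - fr) %o% fc * m[r0, c1] +
      fr %o% (1 - fc) * m[r1, c0] + fr %o% fc * m[r1, c1]
  }
}
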