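#' Multispectral reflectance scene
#'
#' A rank-3 reflectance raster (rows x cols x bands) with band metadata and an
#' optional nodata mask. Reflectances are unitless surface reflectance in
#' `[0, 1]`.
#'
#' @param reflectance numeric array, dim `c(rows, cols, bands)`, values in
#'   `[0, 1]` (values outside are accepted but flagged by [validate_scene()]).
#' @param bands character vector naming the spectral bands, one per slice.
#'   Defaults to the six 10/20 m Sentinel-2-style bands used throughout:
#'   blue, green, red, two red-edge bands and near-infrared.
#' @param mask optional logical matrix (rows x cols); `TRUE` marks valid data.
#' @return an object of class `multispectral_scene`.
#' @export
multispectral_scene <- function(reflectance, bands = DEFAULT_BANDS, mask = NULL) {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3L)
    stop("reflectance must be a 3-d array (rows x cols x bands)")
  if (dim(reflectance)[3] != length(bands))
    stop("number of band names (", length(bands), ") does not match array depth (",
         dim(reflectance)[3], ")")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == dim(reflectance)[1:2]))
      stop("mask must be a logical matrix matching the scene grid")
  }
  dimnames(reflectance) <- list(NULL, NULL, bands)
  structure(list(reflectance = reflectance, bands = bands, mask = mask),
            class = "multispectral_scene")
}

#' @export
dim.multispectral_scene <- function(x) dim(x$reflectance)

#' @export
print.multispectral_scene <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<multispectral_scene> %d x %d pixels, %d bands (%s)\n",
              d[1], d[2], d[3], paste(x$bands, collapse = ", ")))
  cat(sprintf("  reflectance range: [%.4f, %.4f]\n",
              min(x$reflectance), max(x$reflectance)))
  if (!is.null(x$mask))
    cat(sprintf("  masked pixels: %d\n", sum(!x$mask)))
  invisible(x)
}

#' Extract one band of a scene as a matrix
#'
#' @param scene a [multispectral_scene()].
#' @param band band name (e.g. `"band8"`).
#' @return numeric matrix.
#' @export
scene_band <- function(scene, band) {
  stopifnot(inherits(scene, "multispectral_scene"))
  if (!band %in% scene$bands)
    stop("band '", band, "' not present; scene has: ",
         paste(scene$bands, collapse = ", "))
  scene$reflectance[, , match(band, scene$bands)]
}

#' Validate a scene's invariants
#'
#' Checks finiteness and the `[0, 1]` reflectance range.
#' @param scene a [multispectral_scene()].
#' @return `scene`, invisibly; errors otherwise.
#' @export
validate_scene <- function(scene) {
  stopifnot(inherits(scene, "multispectral_scene"))
  if (any(!is.finite(scene$reflectance)))
    stop("scene contains non-finite reflectance values")
  rng <- range(scene$reflectance)
  if (rng[1] < 0 || rng[2] > 1)
    stop(sprintf("reflectance outside [0,1]: range [%.4f, %.4f]", rng[1], rng[2]))
  invisible(scene)
}

#' Integer class-label raster
#'
#' @param values integer matrix of class codes; codes must be present in
#'   `classes`.
#' @param classes named integer vector mapping class names to codes; default
#'   `c(other = 0, corn = 1, soybean = 2)`.
#' @return an object of class `label_raster`.
#' @export
label_raster <- function(values, classes = DEFAULT_CLASSES) {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  bad <- setdiff(unique(as.vector(values)), unname(classes))
  if (length(bad))
    stop("label codes not in class table: ", paste(bad, collapse = ", "))
  structure(list(values = values, classes = classes), class = "label_raster")
}

#' @export
dim.label_raster <- function(x) dim(x$values)

#' @export
print.label_raster <- function(x, ...) {
  tab <- table(factor(x$values, levels = unname(x$classes),
                      labels = names(x$classes)))
  cat(sprintf("<label_raster> %d x %d pixels\n", nrow(x$values), ncol(x$values)))
  for (nm in names(tab))
    cat(sprintf("  %-8s %d (%.1f%%)\n", nm, tab[[nm]],
                100 * tab[[nm]] / length(x$values)))
  invisible(x)
}

stopifnot_aligned <- function(a, b) {
  if (!all(dim(a)[1:2] == dim(b)[1:2]))
    stop("rasters are not aligned: ", paste(dim(a)[1:2], collapse = "x"),
         " vs ", paste(dim(b)[1:2], collapse = "x"))
  invisible(TRUE)
}
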