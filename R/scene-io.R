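# Plain-text persistence. No GeoTIFF-capable package is assumed; scenes are
# stored as one whitespace-separated matrix block per band plus a JSON sidecar
# carrying band names, shape and any provenance (seed, config).

#' Write a scene to a plain-text file
#'
#' The format is a JSON header line followed by one `rows x cols` numeric block
#' per band, bands in scene order. Readable by [read_scene()].
#'
#' @param scene a [multispectral_scene()].
#' @param path output file path.
#' @param meta optional list of extra metadata (seed, generator config, ...)
#'   stored in the header.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path, meta = list()) {
  stopifnot(inherits(scene, "multispectral_scene"))
  d <- dim(scene)
  hdr <- c(list(rows = d[1], cols = d[2], bands = scene$bands), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA), con)
  for (b in seq_len(d[3]))
    write.table(format(scene$reflectance[, , b], digits = 8, trim = TRUE),
                con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scene written by [write_scene()]
#'
#' @param path file path.
#' @return a [multispectral_scene()]; metadata from the header is attached as
#'   attribute `"meta"`.
#' @export
read_scene <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  rows <- hdr$rows; cols <- hdr$cols; bands <- hdr$bands
  vals <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  if (length(vals) != rows * cols * length(bands))
    stop("scene file is truncated or corrupt")
  arr <- array(NA_real_, c(rows, cols, length(bands)))
  per <- rows * cols
  for (b in seq_along(bands)) {
    block <- matrix(vals[((b - 1) * per + 1):(b * per)], nrow = rows, byrow = TRUE)
    arr[, , b] <- block
  }
  sc <- multispectral_scene(arr, bands = bands)
  attr(sc, "meta") <- hdr[setdiff(names(hdr), c("rows", "cols", "bands"))]
  sc
}

#' Write a label raster to a plain-text file
#' @param labels a [label_raster()].
#' @param path output file path.
#' @param meta optional metadata list for the JSON header.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, meta = list()) {
  stopifnot(inherits(labels, "label_raster"))
  hdr <- c(list(rows = nrow(labels$values), cols = ncol(labels$values),
                classes = as.list(labels$classes)), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE), con)
  write.table(labels$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a label raster written by [write_labels()]
#' @param path file path.
#' @return a [label_raster()].
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  vals <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  m <- matrix(as.integer(vals), nrow = hdr$rows, byrow = TRUE)
  label_raster(m, classes = unlist(hdr$classes))
}
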