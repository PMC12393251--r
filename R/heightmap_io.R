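# Height-map file I/O. TIFF stores heights as 32-bit float; PNG stores
# 16-bit integers with an affine height scale in a JSON-like sidecar
# line; CSV stores plain text heights (the format used for small
# text-only fixtures).

#' Write an AFM height map to file
#'
#' `"tiff"` writes 32-bit float grayscale, heights affinely scaled to
#' [0, 1] (round-trips to single precision, ~1e-7 of the height range).
#' `"png"` writes 8-bit grayscale with the same affine scaling
#' (quantized to 1/255 of the height range -- a display format). The
#' scale and offset are stored in a sidecar file `<path>.scale` and
#' applied on read. `"csv"` writes the raw height matrix as
#' comma-separated text (full double precision). The pixel size is
#' stored in a sidecar `<path>.pixel` for all formats.
#'
#' @param image a `height_map`.
#' @param path output path.
#' @param format `"tiff"`, `"png"` or `"csv"` (default from the file
#'   extension).
#' @return `path`, invisibly.
#' @export
write_height_map <- function(image, path, format = NULL) {
  stopifnot(inherits(image, "height_map"))
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     tif = , tiff = "tiff", png = "png", "csv")
  z <- unclass(image)
  if (format %in% c("tiff", "png")) {
    lo <- min(z); hi <- max(z)
    scale <- if (hi > lo) hi - lo else 1
    zs <- (z - lo) / scale
    if (format == "tiff") tiff::writeTIFF(zs, path, bits.per.sample = 32L)
    else png::writePNG(zs, path)
    writeLines(sprintf("offset_nm,scale_nm\n%.10g,%.10g", lo, scale),
               paste0(path, ".scale"))
  } else if (format == "csv") {
    utils::write.table(z, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else .stopf("unknown height-map format: %s", format)
  writeLines(sprintf("%.10g", attr(image, "pixel_nm")),
             paste0(path, ".pixel"))
  invisible(path)
}

#' Read an AFM height map from file
#'
#' Counterpart of [write_height_map()]; `pixel_nm` overrides (or
#' replaces, if no sidecar exists) the stored pixel size.
#'
#' @param path input path.
#' @param pixel_nm pixel size in nm; required when no `<path>.pixel`
#'   sidecar is present.
#' @param format `"tiff"`, `"png"` or `"csv"` (default from extension).
#' @return a `height_map`.
#' @export
read_height_map <- function(path, pixel_nm = NULL, format = NULL) {
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     tif = , tiff = "tiff", png = "png", "csv")
  if (is.null(pixel_nm)) {
    side <- paste0(path, ".pixel")
    if (!file.exists(side))
      .stopf("no pixel size: supply pixel_nm or a %s sidecar", side)
    pixel_nm <- as.numeric(readLines(side, n = 1))
  }
  z <- if (format %in% c("tiff", "png")) {
    m <- if (format == "tiff") tiff::readTIFF(path) else png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    sc <- utils::read.csv(paste0(path, ".scale"))
    m * sc$scale_nm + sc$offset_nm
  } else if (format == "csv") {
    as.matrix(utils::read.table(path, sep = ","))
  } else .stopf("unknown height-map format: %s", format)
  dimnames(z) <- NULL
  height_map(z, pixel_nm)
}
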