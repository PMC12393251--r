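# AFM height-map analysis: flattening, segmentation, classification,
# centroid / centre-of-mass offset distance and relative affinity.
#
# Conventions: a height map is a numeric matrix of heights in nm,
# row-major image coordinates with the origin at the top-left pixel,
# 0-based pixel coordinates at pixel centres; physical distances are
# pixel coordinates times the pixel size in nm.

#' Construct an AFM height map
#'
#' @param z numeric matrix of heights in nm (rows = scan lines).
#' @param pixel_nm pixel size in nm per pixel (> 0).
#' @param metadata optional named list of scan metadata.
#' @return object of class `height_map` (the matrix, with attributes
#'   `pixel_nm` and `metadata`).
#' @export
height_map <- function(z, pixel_nm, metadata = list()) {
  if (!is.matrix(z) || !is.numeric(z)) .stopf("z must be a numeric matrix")
  if (any(!is.finite(z))) .stopf("heights must be finite")
  if (!is.numeric(pixel_nm) || length(pixel_nm) != 1 || pixel_nm <= 0)
    .stopf("pixel_nm must be a positive scalar")
  structure(z, pixel_nm = pixel_nm, metadata = metadata,
            class = c("height_map", "matrix", "array"))
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("AFM height map: %d x %d px, %.4g nm/px, heights %.3g .. %.3g nm\n",
              nrow(x), ncol(x), attr(x, "pixel_nm"), min(x), max(x)))
  invisible(x)
}

.pixel_nm <- function(image) {
  px <- attr(image, "pixel_nm")
  if (is.null(px)) .stopf("image has no pixel_nm attribute; use height_map()")
  px
}

#' Flatten an AFM height map line by line
#'
#' Removes tilt and bow artifacts: for each scan line (row), a polynomial
#' of the given order is fitted to the background pixels of that row --
#' pixels below the row's `background_quantile` height quantile, so
#' molecules do not bias the fit -- and the fitted polynomial is
#' subtracted from the whole row. After flattening the background median
#' is approximately zero; on an image that is pure per-row polynomial
#' background the output is exactly zero, and the operation is idempotent
#' up to noise.
#'
#' @param image a `height_map`.
#' @param order polynomial order, 0, 1 or 2 (default 2).
#' @param background_quantile quantile below which row pixels are treated
#'   as background (default 0.75).
#' @return the flattened `height_map`.
#' @export
flatten <- function(image, order = 2, background_quantile = 0.75) {
  stopifnot(inherits(image, "height_map"))
  if (!order %in% 0:2) .stopf("order must be 0, 1 or 2")
  if (ncol(image) < order + 1)
    .stopf("image has fewer columns (%d) than polynomial coefficients (%d)",
           ncol(image), order + 1)
  z <- unclass(image)
  col_idx <- seq_len(ncol(z))
  for (r in seq_len(nrow(z))) {
    row <- z[r, ]
    bg <- row <= stats::quantile(row, background_quantile, names = FALSE)
    if (sum(bg) < order + 1) bg <- rep(TRUE, length(row))
    if (order == 0) {
      z[r, ] <- row - mean(row[bg])
    } else {
      fit <- stats::lm(row[bg] ~ stats::poly(col_idx[bg], order, raw = TRUE))
      z[r, ] <- row - cbind(1, stats::poly(col_idx, order, raw = TRUE)) %*%
        stats::coef(fit)
    }
  }
  height_map(z, .pixel_nm(image), attr(image, "metadata"))
}

#' Segment supra-threshold molecules in a flattened height map
#'
#' Thresholds the image at `height_threshold` nm, labels connected
#' components, fills any holes inside each component (so a ring mask
#' becomes a solid disk -- the solid connected mask the offset distance
#' is defined on), and measures each region. Connected-component
#' labelling and hole filling use \pkg{EBImage}. Components smaller than
#' `min_pixels` (single-pixel noise specks) are discarded.
#'
#' @param image a flattened `height_map`.
#' @param height_threshold threshold height in nm.
#' @param min_pixels minimum component size in pixels before hole filling
#'   (default 4).
#' @return list of `molecule_region` objects, each a list with `id`,
#'   `pixels` (two-column matrix of 0-based row/col coordinates of the
#'   filled mask), `bbox` (`row_min`, `row_max`, `col_min`, `col_max`),
#'   `area_nm2`, `mean_height_nm` (mean over the filled mask), and
#'   `pixel_nm`. An empty list if nothing exceeds the threshold.
#' @export
segment_molecules <- function(image, height_threshold, min_pixels = 4) {
  stopifnot(inherits(image, "height_map"))
  px <- .pixel_nm(image)
  z <- unclass(image)
  mask <- z > height_threshold
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(mask * 1)
  keep <- which(tabulate(lab[lab > 0]) >= min_pixels)
  if (!length(keep)) return(list())
  lab[!(lab %in% keep)] <- 0L
  filled <- EBImage::fillHull(lab)
  regions <- list()
  for (id in keep) {
    sel <- which(filled == id, arr.ind = TRUE)
    hts <- z[sel]
    regions[[length(regions) + 1]] <- structure(list(
      id = length(regions) + 1L,
      pixels = cbind(row = sel[, 1] - 1L, col = sel[, 2] - 1L),
      bbox = c(row_min = min(sel[, 1]) - 1L, row_max = max(sel[, 1]) - 1L,
               col_min = min(sel[, 2]) - 1L, col_max = max(sel[, 2]) - 1L),
      area_nm2 = nrow(sel) * px^2,
      mean_height_nm = mean(hts),
      pixel_nm = px), class = "molecule_region")
  }
  regions
}

#' Classify a segmented region by area and mean height
#'
#' Decision rule, applied in order: area above `area_max` is an
#' `"aggregate"` (e.g. circular dimers or protein-DNA clusters, excluded
#' from analysis); area below `area_min` is a lone `"protein"`; mean
#' height below `intensity_min` is lone `"dna"` (rings are dimmer than
#' protein-bearing complexes); anything else is a `"complex"`, the
#' candidate class for the offset distance. A `confirmed` flag stands in
#' for the manual-inspection step of real analyses: regions with
#' `confirmed = FALSE` are labelled `"rejected"`.
#'
#' @param region a `molecule_region` from [segment_molecules()].
#' @param thresholds named list with `area_min`, `area_max` (nm^2) and
#'   `intensity_min` (nm); all three are required.
#' @param confirmed logical; manual-confirmation stand-in (default TRUE).
#' @return class label: one of `"dna"`, `"protein"`, `"complex"`,
#'   `"aggregate"`, `"rejected"`.
#' @export
classify_region <- function(region, thresholds, confirmed = TRUE) {
  stopifnot(inherits(region, "molecule_region"))
  need <- c("area_min", "area_max", "intensity_min")
  miss <- setdiff(need, names(thresholds))
  if (length(miss)) .stopf("missing classification threshold(s): %s",
                           paste(miss, collapse = ", "))
  if (!confirmed) return("rejected")
  if (region$area_nm2 > thresholds$area_max) return("aggregate")
  if (region$area_nm2 < thresholds$area_min) return("protein")
  if (region$mean_height_nm < thresholds$intensity_min) return("dna")
  "complex"
}

#' Centroid versus centre-of-mass offset distance of a region
#'
#' The geometric centroid is the unweighted mean of the filled-mask pixel
#' coordinates; the centre of mass is the mean of the same coordinates
#' weighted by pixel height (flattened heights; negative weights are
#' clipped to zero). The offset distance delta is the Euclidean distance
#' between the two, converted to nm via the pixel size. For a
#' protein-marked DNA minicircle, delta is small when the marker sits
#' inside the ring and approaches the apparent ring radius when it sits
#' outside.
#'
#' @param region a `molecule_region`.
#' @param image the `height_map` the region was segmented from.
#' @return list with `delta_nm`, `centroid_nm` and `com_nm` (each
#'   `c(row, col)` in nm).
#' @export
offset_distance <- function(region, image) {
  stopifnot(inherits(region, "molecule_region"), inherits(image, "height_map"))
  px <- .pixel_nm(image)
  pixv <- region$pixels
  w <- pmax(unclass(image)[cbind(pixv[, "row"] + 1L, pixv[, "col"] + 1L)], 0)
  if (sum(w) <= 0) .stopf("degenerate weights: region has no positive intensity")
  centroid <- colMeans(pixv)
  com <- colSums(pixv * w) / sum(w)
  list(delta_nm = sqrt(sum((centroid - com)^2)) * px,
       centroid_nm = centroid * px, com_nm = com * px)
}

#' Region table of a segmented, classified height map
#'
#' Runs [classify_region()] and [offset_distance()] over all regions and
#' assembles the standard region table.
#'
#' @param regions list of `molecule_region` from [segment_molecules()].
#' @param image the source `height_map`.
#' @param thresholds classification thresholds (see [classify_region()]).
#' @return data frame with columns `id`, `area_nm2`, `mean_h_nm`,
#'   `cx_nm`, `cy_nm`, `comx_nm`, `comy_nm`, `delta_nm`, `class`
#'   (x = column direction, y = row direction).
#' @export
region_table <- function(regions, image, thresholds) {
  if (!length(regions))
    return(data.frame(id = integer(), area_nm2 = numeric(),
                      mean_h_nm = numeric(), cx_nm = numeric(),
                      cy_nm = numeric(), comx_nm = numeric(),
                      comy_nm = numeric(), delta_nm = numeric(),
                      class = character()))
  rows <- lapply(regions, function(r) {
    od <- offset_distance(r, image)
    data.frame(id = r$id, area_nm2 = r$area_nm2,
               mean_h_nm = r$mean_height_nm,
               cx_nm = od$centroid_nm[["col"]], cy_nm = od$centroid_nm[["row"]],
               comx_nm = od$com_nm[["col"]], comy_nm = od$com_nm[["row"]],
               delta_nm = od$delta_nm,
               class = classify_region(r, thresholds))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Molecule counts for the relative-affinity statistic
#'
#' @param classes character vector of region class labels (from
#'   [region_table()]).
#' @return object of class `affinity_counts`: list with `N_D` (lone DNA),
#'   `N_P` (lone protein), `N_DP` (complexes).
#' @export
affinity_counts <- function(classes) {
  structure(list(N_D = sum(classes == "dna"),
                 N_P = sum(classes == "protein"),
                 N_DP = sum(classes == "complex")),
            class = "affinity_counts")
}

#' Relative affinity of protein for DNA from scan counts
#'
#' `alpha = N_DP / (N_D * N_P)`: the number of DNA-protein complexes
#' normalized by the numbers of lone DNA minicircles and lone protein
#' molecules in the same scan. Under the assumption that surface-bound
#' counts reflect solution concentrations, alpha is proportional to the
#' association constant. Note alpha is concentration-dependent:
#' duplicating a scan (doubling all three counts) halves alpha.
#'
#' @param counts an `affinity_counts` object, or a list/vector with
#'   elements `N_D`, `N_P`, `N_DP`.
#' @return relative affinity (dimension 1/count).
#' @export
relative_affinity <- function(counts) {
  nd <- counts[["N_D"]]; np <- counts[["N_P"]]; ndp <- counts[["N_DP"]]
  if (is.null(nd) || is.null(np) || is.null(ndp))
    .stopf("counts must provide N_D, N_P and N_DP")
  if (nd <= 0 || np <= 0)
    .stopf("undefined affinity: N_D and N_P must both be positive")
  ndp / (nd * np)
}
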