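# Synthetic AFM scenes with analytic ground truth.
#
# A molecule is one or more features sharing a molecule id: a ring (a
# Gaussian tube of given half-width around a circle, emulating a
# deposited DNA minicircle) and/or a blob (an isotropic 2D Gaussian,
# emulating a globular protein). Scenes add a per-row polynomial
# background and white height noise. Ground truth per molecule includes
# its class and, for ring+blob complexes, the offset distance computed by
# brute-force pixel sums on the noiseless single-molecule image.

#' Specification of a synthetic AFM scene
#'
#' @param image_px image size in pixels, `c(rows, cols)` or a scalar.
#' @param pixel_nm pixel size in nm per pixel.
#' @param features data frame with one row per feature: columns
#'   `molecule` (integer id grouping features into molecules), `type`
#'   (`"ring"` or `"blob"`), `x_nm`, `y_nm` (centre, x = column
#'   direction, y = row direction, from the top-left pixel centre),
#'   `height_nm` (peak height), `radius_nm` (ring centre-line radius, or
#'   Gaussian sigma for blobs) and `width_nm` (ring tube sigma; ignored
#'   for blobs).
#' @param background_coef per-row polynomial background coefficients
#'   `c(c0, c1, c2, ...)` in nm, evaluated in the normalized column
#'   coordinate u in [0, 1]: `bg = c0 + c1 u + c2 u^2 + ...`. Either a
#'   single vector (every row identical) or a matrix with one row per
#'   scan line.
#' @param noise_sd white height-noise SD in nm (>= 0).
#' @param mask_threshold_nm height threshold used to define ground-truth
#'   masks (default 0.35).
#' @param seed random seed for the noise.
#' @return object of class `afm_scene_spec`.
#' @export
afm_scene_spec <- function(image_px = 256, pixel_nm = 0.5, features,
                           background_coef = 0, noise_sd = 0,
                           mask_threshold_nm = 0.35, seed = 1) {
  if (length(image_px) == 1) image_px <- c(image_px, image_px)
  stopifnot(is.data.frame(features))
  need <- c("molecule", "type", "x_nm", "y_nm", "height_nm", "radius_nm",
            "width_nm")
  miss <- setdiff(need, names(features))
  if (length(miss)) .stopf("features is missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (!all(features$type %in% c("ring", "blob")))
    .stopf("feature type must be 'ring' or 'blob'")
  ext <- (image_px[c(2, 1)] - 1) * pixel_nm
  if (any(features$x_nm < 0 | features$x_nm > ext[1] |
          features$y_nm < 0 | features$y_nm > ext[2]))
    .stopf("feature centres must lie within the image")
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  structure(list(image_px = image_px, pixel_nm = pixel_nm,
                 features = features, background_coef = background_coef,
                 noise_sd = noise_sd, mask_threshold_nm = mask_threshold_nm,
                 seed = seed),
            class = "afm_scene_spec")
}

# noiseless height contribution of a set of features, as a matrix
.render_features <- function(features, image_px, pixel_nm) {
  z <- matrix(0, image_px[1], image_px[2])
  xc <- ((seq_len(image_px[2]) - 1) * pixel_nm)   # column coordinate, nm
  yc <- ((seq_len(image_px[1]) - 1) * pixel_nm)   # row coordinate, nm
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    dx2 <- outer(rep(1, image_px[1]), (xc - f$x_nm)^2)
    dy2 <- outer((yc - f$y_nm)^2, rep(1, image_px[2]))
    d <- sqrt(dx2 + dy2)
    z <- z + if (f$type == "ring")
      f$height_nm * exp(-(d - f$radius_nm)^2 / (2 * f$width_nm^2))
    else
      f$height_nm * exp(-d^2 / (2 * f$radius_nm^2))
  }
  z
}

# brute-force centroid / centre-of-mass offset of a noiseless molecule
# image: threshold, fill holes, unweighted vs height-weighted pixel sums
.truth_delta <- function(z, threshold, pixel_nm) {
  mask <- EBImage::fillHull((z > threshold) * 1)
  sel <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(sel)) return(NA_real_)
  w <- z[sel]
  centroid <- colMeans(sel)
  com <- colSums(sel * w) / sum(w)
  sqrt(sum((centroid - com)^2)) * pixel_nm
}

#' Render a synthetic AFM scene with ground truth
#'
#' Builds the height map (sum of feature profiles + per-row polynomial
#' background + white noise) and a ground-truth table: one row per
#' molecule with its class (`"dna"` for a lone ring, `"protein"` for a
#' lone blob, `"complex"` for ring+blob) and, for complexes, the true
#' offset distance from brute-force pixel sums on that molecule's
#' noiseless image. Molecules whose thresholded masks touch another
#' molecule's are flagged `overlap = TRUE`.
#'
#' @param spec an [afm_scene_spec()].
#' @return list with `image` (a `height_map`), `truth` (data frame:
#'   `molecule`, `class`, `true_delta_nm`, `overlap`) and `spec`.
#' @export
make_afm_scene <- function(spec) {
  stopifnot(inherits(spec, "afm_scene_spec"))
  np <- spec$image_px
  mols <- sort(unique(spec$features$molecule))
  z_mol <- matrix(0, np[1], np[2])
  truth <- list()
  masks <- list()
  for (m in mols) {
    fm <- spec$features[spec$features$molecule == m, ]
    zm <- .render_features(fm, np, spec$pixel_nm)
    z_mol <- z_mol + zm
    cls <- if (all(fm$type == "ring")) "dna"
           else if (all(fm$type == "blob")) "protein" else "complex"
    truth[[length(truth) + 1]] <- data.frame(
      molecule = m, class = cls,
      true_delta_nm = if (cls == "complex")
        .truth_delta(zm, spec$mask_threshold_nm, spec$pixel_nm) else NA_real_)
    masks[[length(masks) + 1]] <- zm > spec$mask_threshold_nm
  }
  truth <- do.call(rbind, truth)
  # overlap flag: a molecule's mask intersects the union of the others'
  truth$overlap <- vapply(seq_along(masks), function(i) {
    others <- Reduce(`|`, masks[-i], matrix(FALSE, np[1], np[2]))
    any(masks[[i]] & others)
  }, logical(1))
  if (any(truth$overlap))
    warning("synthetic scene contains overlapping molecules; ground truth for those rows is unreliable")
  # background
  bc <- spec$background_coef
  if (is.null(dim(bc))) bc <- matrix(bc, np[1], length(bc), byrow = TRUE)
  u <- (seq_len(np[2]) - 1) / max(np[2] - 1, 1)
  bg <- bc %*% t(outer(u, seq_len(ncol(bc)) - 1, `^`))
  z <- z_mol + bg
  if (spec$noise_sd > 0)
    z <- z + .with_seed(spec$seed,
                        matrix(stats::rnorm(length(z), 0, spec$noise_sd),
                               np[1], np[2]))
  list(image = height_map(z, spec$pixel_nm), truth = truth, spec = spec)
}

#' Randomly populated synthetic AFM scene
#'
#' Places lone rings ("DNA"), lone blobs ("protein") and ring+blob
#' complexes at jittered grid positions (so molecules never overlap) and
#' renders the scene. Complex blobs sit at a radial offset
#' `blob_offset_frac * ring_radius_nm` from the ring centre (1 = on the
#' rim, emulating an outside-facing marker; 0 = centred, inside).
#'
#' @param n_dna,n_protein,n_complex molecule counts.
#' @param image_px,pixel_nm image geometry (defaults 400 px at 1 nm/px).
#' @param ring_radius_nm,ring_height_nm,ring_width_nm ring geometry
#'   (defaults 2, 0.7 and 1.2 nm -- a ~2 nm apparent-radius minicircle).
#' @param blob_sigma_nm,blob_height_nm blob geometry (defaults 1.2 and
#'   4 nm; globular protein images much taller and more compact than DNA).
#' @param blob_offset_frac radial blob offset for complexes, as a
#'   fraction of the ring radius (default 1).
#' @param background_coef,noise_sd,seed as in [afm_scene_spec()]
#'   (defaults: flat background, 0.08 nm noise).
#' @return as [make_afm_scene()].
#' @export
random_afm_scene <- function(n_dna, n_protein, n_complex,
                             image_px = 400, pixel_nm = 1,
                             ring_radius_nm = 2, ring_height_nm = 0.7,
                             ring_width_nm = 1.2, blob_sigma_nm = 1.2,
                             blob_height_nm = 4, blob_offset_frac = 1,
                             background_coef = 0, noise_sd = 0.08, seed = 1) {
  if (length(image_px) == 1) image_px <- c(image_px, image_px)
  n <- n_dna + n_protein + n_complex
  spacing_nm <- 16
  ext <- (image_px - 1) * pixel_nm
  nx <- floor((ext[2] - spacing_nm) / spacing_nm)
  ny <- floor((ext[1] - spacing_nm) / spacing_nm)
  if (nx * ny < n) .stopf("image too small for %d molecules at %g nm spacing",
                          n, spacing_nm)
  feats <- .with_seed(seed, {
    slots <- sample(nx * ny, n)
    gx <- ((slots - 1) %% nx) * spacing_nm + spacing_nm / 2 +
      stats::runif(n, -2, 2)
    gy <- ((slots - 1) %/% nx) * spacing_nm + spacing_nm / 2 +
      stats::runif(n, -2, 2)
    cls <- rep(c("dna", "protein", "complex"), c(n_dna, n_protein, n_complex))
    ang <- stats::runif(n, 0, 2 * pi)
    rows <- list()
    for (i in seq_len(n)) {
      if (cls[i] %in% c("dna", "complex"))
        rows[[length(rows) + 1]] <- data.frame(
          molecule = i, type = "ring", x_nm = gx[i], y_nm = gy[i],
          height_nm = ring_height_nm, radius_nm = ring_radius_nm,
          width_nm = ring_width_nm)
      if (cls[i] %in% c("protein", "complex")) {
        off <- if (cls[i] == "complex")
          blob_offset_frac * ring_radius_nm else 0
        rows[[length(rows) + 1]] <- data.frame(
          molecule = i, type = "blob",
          x_nm = gx[i] + off * cos(ang[i]), y_nm = gy[i] + off * sin(ang[i]),
          height_nm = blob_height_nm, radius_nm = blob_sigma_nm,
          width_nm = NA_real_)
      }
    }
    do.call(rbind, rows)
  })
  make_afm_scene(afm_scene_spec(image_px, pixel_nm, feats,
                                background_coef = background_coef,
                                noise_sd = noise_sd, seed = seed + 1))
}

#' Default classification thresholds for the synthetic scene geometry
#'
#' Area and intensity cuts bracketing the default feature sizes of
#' [random_afm_scene()]: a lone blob's thresholded footprint is ~22 nm^2,
#' a filled lone ring ~37-41 nm^2 and a complex larger still, so
#' `area_min = 30` separates protein from DNA-bearing regions; rings
#' without protein average ~0.6 nm over their filled mask while
#' protein-bearing complexes exceed 1 nm, so `intensity_min = 0.85`
#' separates them; `area_max = 150` rejects aggregates. Real-data
#' thresholds should always be supplied explicitly.
#'
#' @return named list with `area_min`, `area_max` (nm^2) and
#'   `intensity_min` (nm).
#' @export
default_afm_thresholds <- function() {
  list(area_min = 30, area_max = 150, intensity_min = 0.85)
}
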