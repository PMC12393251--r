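# Poloidal angle of a tracked phosphate from minicircle coordinates.
#
# The construction uses only internal coordinates of the frame, so the
# angle is invariant under rigid rotations/translations of the whole
# molecule. Sign conventions: the in-plane axis points from P0 through the
# circle, so positive horizontal displacement means "inside the circle"
# and a poloidal angle of 0 means the tracked phosphate is at its
# innermost position; 180 degrees means outermost.

# precompute frame-independent site indices for a tracked nucleotide
.poloidal_index <- function(sites, N, tracked) {
  if (tracked < 0 || tracked >= N) .stopf("tracked nucleotide out of [0, N)")
  qs <- (tracked + round(N * (1:3) / 4)) %% N
  ord <- order(sites$site_id)
  sites <- sites[ord, ]
  key <- paste(sites$strand, sites$nt, sites$atom)
  p_of <- function(nt) match(paste(1, nt, "P"), key)
  iP <- vapply(c(tracked, qs), p_of, integer(1))
  if (anyNA(iP)) .stopf("frame is missing reference phosphates")
  # 10-bp segment centred on the tracked nucleotide: 5 bp on each side of
  # P0 (offsets -5 .. +4 relative to the tracked index; P0, the 5'
  # phosphate of the tracked nucleotide, sits at the segment midpoint),
  # both strands, all three atoms
  seg_nt <- (tracked + (-5:4)) %% N
  iseg <- which(sites$nt %in% seg_nt)
  list(P0 = iP[1], P14 = iP[2], P12 = iP[3], P34 = iP[4],
       seg = iseg, ref_nt = c(tracked, qs))
}

# core computation shared by the public functions; xyz rows = site ids
.poloidal_core <- function(xyz, idx) {
  P0 <- xyz[idx$P0, ]
  v12 <- xyz[idx$P12, ] - P0
  n12 <- sqrt(sum(v12^2))
  if (n12 < 1e-6) .stopf("degenerate frame: P0 and P1/2 coincide")
  xhat <- v12 / n12
  v34 <- xyz[idx$P34, ] - xyz[idx$P14, ]
  zraw <- v34 - sum(v34 * xhat) * xhat   # Gram-Schmidt against xhat
  zhat <- .unit(zraw, "z-axis (P1/4 - P3/4 chord parallel to x-axis)")
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  C <- colMeans(xyz[idx$seg, , drop = FALSE])
  O <- C - sum((C - P0) * zhat) * zhat   # project onto x-y plane through P0
  v <- P0 - O
  r <- sqrt(sum(v^2))
  list(xhat = xhat, yhat = yhat, zhat = zhat, origin = O,
       phi = atan2(sum(v * yhat), sum(v * xhat)) * RAD2DEG,
       x = sum(v * xhat), r = r)
}

.frame_parts <- function(frame) {
  if (inherits(frame, "conformation")) frame <- as_cg_frame(frame)
  stopifnot(inherits(frame, "cg_frame"))
  frame
}

#' Body-fixed reference axes of a minicircle frame
#'
#' Builds the orthonormal molecule-fixed frame used for the poloidal
#' angle. Four roughly equidistant strand-1 phosphates are selected: P0 at
#' the tracked nucleotide and P1/4, P1/2, P3/4 at offsets `round(N k / 4)`
#' (mod N), k = 1..3. The x-axis is the unit vector from P0 toward P1/2
#' (pointing through the circle, so the interior is at positive x); the
#' z-axis is the P1/4 to P3/4 chord, Gram-Schmidt-orthogonalized against
#' the x-axis; the y-axis is their cross product `z x x`. The origin O is
#' the projection, onto the x-y plane through P0, of the centroid of all
#' S/P/B sites of the 10 bp centred on the tracked nucleotide (5 bp on
#' each side, both strands). Both P0 and O lie in the x-y plane.
#'
#' @param frame a `cg_frame` (see [get_frame()], [as_cg_frame()]).
#' @param tracked tracked nucleotide index, 0-based, in `[0, N)`.
#' @return list of class `minicircle_axes`: unit vectors `xhat`, `yhat`,
#'   `zhat`, `origin` (Angstrom), and `ref_nt` (the four reference
#'   nucleotide indices, tracked first).
#' @export
reference_axes <- function(frame, tracked) {
  frame <- .frame_parts(frame)
  idx <- .poloidal_index(frame$sites, frame$N, tracked)
  core <- .poloidal_core(frame$xyz, idx)
  structure(list(xhat = core$xhat, yhat = core$yhat, zhat = core$zhat,
                 origin = core$origin, ref_nt = idx$ref_nt),
            class = "minicircle_axes")
}

#' Poloidal angle of the tracked phosphate in one frame
#'
#' The angle of P0 about the local helix axis, measured in the body-fixed
#' frame of [reference_axes()]:
#' `phi = atan2((P0 - O) . yhat, (P0 - O) . xhat)`, in degrees wrapped to
#' (-180, 180]. `phi = 0` is the innermost position, `phi = 180` the
#' outermost.
#'
#' @inheritParams reference_axes
#' @return angle in degrees in (-180, 180].
#' @export
poloidal_angle <- function(frame, tracked) {
  frame <- .frame_parts(frame)
  idx <- .poloidal_index(frame$sites, frame$N, tracked)
  core <- .poloidal_core(frame$xyz, idx)
  if (core$r < 1e-6) .stopf("undefined angle: P0 coincides with the origin O")
  wrap_angle(core$phi)
}

#' Signed horizontal displacement of the tracked phosphate
#'
#' `x = (P0 - O) . xhat` in Angstrom; positive values place the phosphate
#' inside the minicircle, negative outside. Identically
#' `x = |P0 - O| cos(phi)`.
#'
#' @inheritParams reference_axes
#' @return displacement in Angstrom.
#' @export
horizontal_displacement <- function(frame, tracked) {
  frame <- .frame_parts(frame)
  idx <- .poloidal_index(frame$sites, frame$N, tracked)
  core <- .poloidal_core(frame$xyz, idx)
  if (core$r < 1e-6) .stopf("undefined displacement: P0 coincides with the origin O")
  core$x
}

#' Per-frame poloidal series of a trajectory
#'
#' Applies the poloidal-angle construction to every frame of a
#' trajectory, returning time, angle and signed horizontal displacement
#' of the tracked phosphate.
#'
#' @param traj a `cg_trajectory`.
#' @param tracked tracked nucleotide index (0-based).
#' @param burn_ns burn-in time removed from the start (default 0; see
#'   [trim_burn_in()]).
#' @return a data frame of class `poloidal_series` with columns
#'   `time_ns`, `phi_deg`, `x_A` and attribute `tracked`.
#' @export
poloidal_series <- function(traj, tracked, burn_ns = 0) {
  stopifnot(inherits(traj, "cg_trajectory"))
  idx <- .poloidal_index(traj$sites, traj$N, tracked)
  nf <- length(traj$frames)
  phi <- numeric(nf); x <- numeric(nf)
  for (i in seq_len(nf)) {
    core <- .poloidal_core(traj$frames[[i]], idx)
    phi[i] <- core$phi
    x[i] <- core$x
  }
  out <- data.frame(time_ns = traj$times, phi_deg = wrap_angle(phi), x_A = x)
  class(out) <- c("poloidal_series", "data.frame")
  attr(out, "tracked") <- tracked
  if (burn_ns > 0) out <- trim_burn_in(out, burn_ns) else out
}

#' Remove equilibration frames from a poloidal series
#'
#' Drops all frames with `time_ns < t_burn`. The default of 5 ns reflects
#' the time minicircle poloidal-angle distributions typically need to
#' reach equilibrium in coarse-grained runs.
#'
#' @param series a `poloidal_series`.
#' @param t_burn burn-in time in ns (>= 0; default 5).
#' @return the trimmed `poloidal_series`.
#' @export
trim_burn_in <- function(series, t_burn = 5) {
  stopifnot(is.data.frame(series), "time_ns" %in% names(series))
  if (t_burn < 0) .stopf("t_burn must be non-negative")
  if (t_burn == 0) return(series)
  keep <- series$time_ns >= t_burn
  if (!any(keep)) .stopf("empty series: burn-in (%g ns) removes every frame", t_burn)
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a poloidal series as CSV
#'
#' Columns `time_ns`, `phi_deg`, `x_A`.
#'
#' @param series a `poloidal_series`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `poloidal_series` (reader).
#' @export
write_poloidal_series <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("time_ns", "phi_deg", "x_A")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_poloidal_series
#' @export
read_poloidal_series <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("poloidal_series", "data.frame")
  out
}
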