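#' Helical parameter table for a three-site-per-nucleotide DNA model
#'
#' A `helix_params` object holds, for each of the six atom types (sugar S,
#' phosphate P and base B on each of the two strands), the cylindrical
#' parameters of its ideal helical trajectory -- radius `r` (Angstrom),
#' angular offset `theta0` (degrees) and rise offset `z0` (Angstrom) --
#' together with the global base-pair step twist (degrees per step) and step
#' rise (Angstrom per step). Site `(i, n)` of an ideal linear duplex lies at
#' `(r_i cos(n * twist + theta0_i), r_i sin(n * twist + theta0_i),
#' n * rise + z0_i)`.
#'
#' @param table data frame with columns `strand` (1 or 2), `atom`
#'   (`"S"`, `"P"` or `"B"`), `r`, `theta0`, `z0`. Exactly one row per
#'   (strand, atom) combination; the two strands are independent entries,
#'   no mirroring is assumed.
#' @param twist base-pair step twist in degrees, in (0, 360).
#' @param rise base-pair step rise in Angstrom, positive.
#' @return an object of class `helix_params`.
#' @seealso [default_helix_parameters()], [build_linear_helix()]
#' @export
helix_parameters <- function(table, twist, rise) {
  stopifnot(is.data.frame(table))
  need <- c("strand", "atom", "r", "theta0", "z0")
  if (!all(need %in% names(table)))
    .stopf("helix parameter table must have columns: %s",
           paste(need, collapse = ", "))
  table <- table[order(table$strand, match(table$atom, c("S", "P", "B"))), need]
  key <- paste(table$strand, table$atom)
  want <- paste(rep(1:2, each = 3), rep(c("S", "P", "B"), 2))
  if (!identical(sort(key), sort(want)))
    .stopf("table must contain exactly one row per strand/atom combination")
  if (any(table$r <= 0)) .stopf("all radii must be positive")
  if (!is.numeric(rise) || length(rise) != 1 || rise <= 0)
    .stopf("`rise` must be a positive scalar")
  if (!is.numeric(twist) || length(twist) != 1 || twist <= 0 || twist >= 360)
    .stopf("`twist` must lie strictly between 0 and 360 degrees")
  rownames(table) <- NULL
  structure(list(table = table, twist = twist, rise = rise),
            class = "helix_params")
}

#' Default B-DNA helical parameters
#'
#' A canonical-B-form parameter set for the three-site model: 3.4 Angstrom
#' rise, 10.5 bp per turn, sugar radius 9.2, phosphate radius 9.7 and base
#' radius 4.0 Angstrom. The strand-2 angular offsets are placed 150 degrees
#' from strand 1 so the two backbones separate the cylinder into distinct
#' major (210 degrees) and minor (150 degrees) grooves. Phosphates trail
#' their sugar by half a step along the backbone. All values are
#' overridable by constructing a [helix_parameters()] table directly.
#'
#' @param bp_per_turn helical period in bp per turn used for the default
#'   twist (default 10.5).
#' @return a `helix_params` object.
#' @export
default_helix_parameters <- function(bp_per_turn = 10.5) {
  tab <- data.frame(
    strand = c(1, 1, 1, 2, 2, 2),
    atom   = c("S", "P", "B", "S", "P", "B"),
    r      = c(9.2, 9.7, 4.0, 9.2, 9.7, 4.0),
    theta0 = c(0.0, -17.1, 9.0, 150.0, 167.1, 141.0),
    z0     = c(0.0, -1.7, 0.2, 0.6, 2.3, 0.4)
  )
  helix_parameters(tab, twist = 360 / bp_per_turn, rise = 3.4)
}

#' @export
print.helix_params <- function(x, ...) {
  cat("Helical parameters (3-site DNA model)\n")
  cat(sprintf("  step twist: %.4f deg/bp   step rise: %.3f A/bp\n",
              x$twist, x$rise))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Derive helical parameters from a reference linear duplex
#'
#' Recovers a [helix_parameters()] table from an axis-aligned ideal (or
#' near-ideal) linear duplex, the inverse of [build_linear_helix()]. The
#' step twist and rise are estimated from the strand-1 sugar trajectory:
#' the rise as the mean successive z-spacing and the twist from the mean
#' sugar-sugar distance together with the rise (`d^2 = (2 r sin(twist/2))^2
#' + rise^2`). Per-atom-type radius, angular offset and rise offset are
#' then the means over all base-pair indices `n` of the cylindrical
#' residuals `(sqrt(x^2+y^2), azimuth - n * twist, z - n * rise)`, the
#' angular part averaged circularly. Averaging over `n` means a small
#' perturbation of a single site moves the recovered parameters by less
#' than the perturbation itself.
#'
#' @param reference a `conformation` from [build_linear_helix()] (or any
#'   linear duplex whose helix axis is the z-axis), with at least 3 bp.
#' @return a `helix_params` object; on ideal input it reproduces the
#'   generating parameters to better than 1e-6.
#' @export
derive_helix_parameters <- function(reference) {
  stopifnot(inherits(reference, "conformation"))
  N <- attr(reference, "N")
  if (N < 3) .stopf("insufficient data: need at least 3 bp, got %d", N)
  sites <- reference$sites
  s1 <- sites[sites$strand == 1 & sites$atom == "S", ]
  s1 <- s1[order(s1$nt), ]
  xyz <- as.matrix(s1[, c("x", "y", "z")])
  rise <- mean(diff(xyz[, 3]))
  d <- sqrt(rowSums((xyz[-1, ] - xyz[-N, ])^2))
  rS <- mean(sqrt(xyz[, 1]^2 + xyz[, 2]^2))
  # sugar-sugar distance -> twist: d^2 = (2 r sin(tw/2))^2 + rise^2
  sin_half <- sqrt(pmax(mean(d)^2 - rise^2, 0)) / (2 * rS)
  if (sin_half >= 1) .stopf("reference geometry is not helical")
  twist <- 2 * asin(sin_half) * RAD2DEG

  derive_one <- function(strand, atom) {
    a <- sites[sites$strand == strand & sites$atom == atom, ]
    a <- a[order(a$nt), ]
    r <- mean(sqrt(a$x^2 + a$y^2))
    phase <- atan2(a$y, a$x) * RAD2DEG - a$nt * twist
    ph <- atan2(mean(sin(phase * DEG2RAD)), mean(cos(phase * DEG2RAD))) * RAD2DEG
    z0 <- mean(a$z - a$nt * rise)
    c(r = r, theta0 = ph, z0 = z0)
  }
  grid <- expand.grid(atom = c("S", "P", "B"), strand = 1:2,
                      stringsAsFactors = FALSE)
  est <- t(mapply(derive_one, grid$strand, grid$atom))
  tab <- data.frame(strand = grid$strand, atom = grid$atom,
                    r = est[, "r"], theta0 = est[, "theta0"], z0 = est[, "z0"])
  helix_parameters(tab, twist = twist, rise = rise)
}
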