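#' Build an ideal linear coarse-grained DNA duplex
#'
#' Places every site of a three-site-per-nucleotide duplex on its ideal
#' helical trajectory: site of type `i` at base-pair index `n` sits at
#' `x = r_i cos(n * twist + theta0_i)`, `y = r_i sin(n * twist + theta0_i)`,
#' `z = n * rise + z0_i`, with the helix axis along z. Both strands emit a
#' sugar, a phosphate and a base for every nucleotide (6N sites), so that a
#' subsequently closed circle has a complete backbone. Nucleotides are
#' 0-based; strand 1 runs 5' to 3' with increasing `n`, strand 2 is its
#' antiparallel complement, nucleotide `n` of strand 2 pairing with
#' nucleotide `n` of strand 1.
#'
#' @param params a [helix_parameters()] object.
#' @param N number of base pairs (>= 1).
#' @param sequence strand-1 sequence, a length-`N` string over A/C/G/T.
#' @return an object of class `conformation`: a list with element `sites`
#'   (data frame: `site_id`, `strand`, `nt`, `atom`, `base`, `x`, `y`, `z`)
#'   and attributes `N`, `sequence`, `params`, `circular = FALSE`.
#' @examples
#' conf <- build_linear_helix(default_helix_parameters(), 21,
#'                            strrep("ACGTACG", 3))
#' head(conf$sites)
#' @export
build_linear_helix <- function(params, N, sequence) {
  stopifnot(inherits(params, "helix_params"))
  if (!.is_count(N) || N < 1) .stopf("N must be a positive integer")
  .validate_sequence(sequence, N)
  seq1 <- strsplit(sequence, "")[[1]]
  seq2 <- strsplit(.complement(sequence), "")[[1]]  # strand-2 base pairing nt n
  tab <- params$table
  n <- 0:(N - 1)
  blocks <- lapply(seq_len(nrow(tab)), function(k) {
    ang <- (n * params$twist + tab$theta0[k]) * DEG2RAD
    data.frame(
      strand = tab$strand[k], nt = n, atom = tab$atom[k],
      base = if (tab$strand[k] == 1) seq1 else seq2,
      x = tab$r[k] * cos(ang),
      y = tab$r[k] * sin(ang),
      z = n * params$rise + tab$z0[k]
    )
  })
  sites <- do.call(rbind, blocks)
  sites <- sites[order(sites$strand, sites$nt, match(sites$atom, c("P", "S", "B"))), ]
  sites <- cbind(site_id = seq_len(nrow(sites)), sites)
  rownames(sites) <- NULL
  structure(list(sites = sites), N = N, sequence = sequence, params = params,
            circular = FALSE, class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("Coarse-grained DNA conformation: %d bp, %d sites, %s\n",
              attr(x, "N"), nrow(x$sites),
              if (isTRUE(attr(x, "circular"))) "circular" else "linear"))
  invisible(x)
}

# row index of a site; vectorized over nt
.site_index <- function(sites, strand, nt, atom) {
  idx <- match(paste(strand, nt, atom),
               paste(sites$strand, sites$nt, sites$atom))
  if (anyNA(idx)) .stopf("site (%s) not found in conformation",
                         paste(strand, nt[which(is.na(idx))[1]], atom))
  idx
}

#' Choose a closure-compatible step twist for a minicircle
#'
#' A covalently closed duplex must contain an integer number of helical
#' turns (the linking number Lk). Given a target step twist (default the
#' B-DNA value 360/10.5 degrees per bp), the nearest integer number of
#' turns is `Lk = round(N * target / 360)` and the adjusted uniform step
#' twist is `Lk * 360 / N`, which makes `N * twist` an exact multiple of
#' 360 so the closed helix is continuous across the ligation point.
#'
#' @param N minicircle size in bp (>= 3).
#' @param target_twist desired step twist in degrees per bp
#'   (default `360/10.5`).
#' @return list with `twist` (degrees per step) and `Lk` (integer turns).
#' @examples
#' choose_circle_twist(105)  # Lk = 10, twist = 240/7 ~ 34.29 deg
#' choose_circle_twist(90)   # Lk = 9,  twist = 36 deg
#' @export
choose_circle_twist <- function(N, target_twist = 360 / 10.5) {
  if (!.is_count(N) || N < 3) .stopf("N must be an integer >= 3")
  Lk <- round(N * target_twist / 360)
  list(twist = Lk * 360 / N, Lk = as.integer(Lk))
}

#' Bend a linear duplex into a planar minicircle
#'
#' Translates the molecule so its geometric centre (unit site masses) sits
#' at `(0, R, 0)`, then rotates each cross-section rigidly about the
#' x-axis by its arc angle: `(x, y, z) -> (x, y cos(z/R), y sin(z/R))`.
#' The map fixes `(0, R, 0)`, preserves x exactly and preserves each
#' site's distance from the x-axis (`sqrt(y'^2 + z'^2) = y`), and is
#' length-preserving along the `y = R` centreline; sites inside/outside
#' the centreline are compressed/stretched along the arc, which is the
#' physical bending strain. With `R = N * rise / (2 * pi)` (the default)
#' the arc closes after exactly one circumference, site `n = N`
#' coinciding with `n = 0`.
#'
#' @param conf a linear `conformation`.
#' @param R bend radius in Angstrom; default `N * rise / (2 * pi)` so the
#'   contour closes.
#' @return a `conformation` with attribute `circular = TRUE` and attribute
#'   `radius = R`.
#' @export
circularize <- function(conf, R = NULL) {
  stopifnot(inherits(conf, "conformation"))
  if (isTRUE(attr(conf, "circular"))) .stopf("conformation is already circular")
  params <- attr(conf, "params")
  N <- attr(conf, "N")
  if (is.null(R)) {
    if (is.null(params)) .stopf("R must be given when the conformation carries no helix parameters")
    R <- N * params$rise / (2 * pi)
  }
  sites <- conf$sites
  ctr <- c(mean(sites$x), mean(sites$y), mean(sites$z))
  x <- sites$x - ctr[1]
  y <- sites$y - ctr[2] + R
  z <- sites$z - ctr[3]
  if (any(y <= 0)) {
    bad <- sites$site_id[which(y <= 0)[1]]
    .stopf("singular transform: site %d has non-positive bending radius (helix radius exceeds R = %.3f A)",
           bad, R)
  }
  sites$x <- x
  sites$y <- y * cos(z / R)
  sites$z <- y * sin(z / R)
  out <- structure(list(sites = sites), N = N,
                   sequence = attr(conf, "sequence"), params = params,
                   circular = TRUE, radius = R, class = "conformation")
  out
}

#' Build a closed minicircle conformation and topology in one call
#'
#' Convenience wrapper: adjusts the step twist to an integer linking
#' number with [choose_circle_twist()], builds the ideal linear duplex,
#' bends it into a planar circle with [circularize()], and closes the
#' covalent topology with [close_topology()].
#'
#' @param N minicircle size in bp.
#' @param sequence strand-1 sequence (length `N`); default a deterministic
#'   repeat filled to length.
#' @param params base [helix_parameters()]; its twist is replaced by the
#'   closure-compatible value.
#' @param target_twist target step twist passed to [choose_circle_twist()].
#' @param radius bend radius in Angstrom passed to [circularize()];
#'   default `N * rise / (2 * pi)`. Small circles (`N` below ~20 bp at
#'   B-DNA rise) need an explicit radius larger than the backbone helix
#'   radius.
#' @return list with `conformation` (circular), `topology` (closed),
#'   `twist`, `Lk`, `radius`.
#' @export
build_minicircle <- function(N, sequence = NULL,
                             params = default_helix_parameters(),
                             target_twist = 360 / 10.5, radius = NULL) {
  ct <- choose_circle_twist(N, target_twist)
  params <- helix_parameters(params$table, twist = ct$twist, rise = params$rise)
  if (is.null(sequence))
    sequence <- substr(strrep("ACGT", ceiling(N / 4)), 1, N)
  lin <- build_linear_helix(params, N, sequence)
  circ <- circularize(lin, radius)
  topo <- close_topology(build_topology(lin), circ)
  list(conformation = circ, topology = topo,
       twist = ct$twist, Lk = ct$Lk, radius = attr(circ, "radius"))
}
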