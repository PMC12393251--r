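#' Bonded topology of a coarse-grained duplex
#'
#' Builds the bond, angle and dihedral records of an *open* (linear)
#' three-site-per-nucleotide duplex. Records carry class labels only; no
#' force-field parameters are attached. Connectivity per strand, written
#' in the strand's own 5' to 3' order (strand 1 with increasing `n`,
#' strand 2 with decreasing `n`):
#'
#' * bonds: `SB` (sugar-base, every nucleotide), `SP` (sugar to the 3'
#'   phosphate), `PS` (phosphate to its own sugar), `BB` (base stacking).
#'   The 5'-terminal phosphate of an open strand is unbonded -- it is the
#'   free 5'-phosphate that ligation consumes.
#' * angles: `SPS` at every bridging phosphate, `5PSB3` (5' phosphate -
#'   sugar - base) and `3PSB5` (3' phosphate - sugar - base) at every
#'   sugar where the flanking bonds exist.
#' * dihedrals: backbone `SPSP` and `PSPS`, and the four base-coupled
#'   patterns `SPSB53`, `SPSB35`, `PSBB53`, `PSBB35`.
#'
#' These rules are chosen so that closing an N-bp circle adds exactly 6
#' bonds, 6 angles and 16 dihedrals (see [close_topology()]).
#'
#' @param conf a `conformation` (linear or circular coordinates; the
#'   topology itself is built open).
#' @return an object of class `topology`: list with data frames `bonds`
#'   (`i`, `j`, `class`), `angles` (`i`, `j`, `k`, `class`), `dihedrals`
#'   (`i`, `j`, `k`, `l`, `class`) and logical `closed`.
#' @export
build_topology <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  N <- attr(conf, "N")
  sites <- conf$sites
  bonds <- list(); angles <- list(); dihedrals <- list()
  for (strand in 1:2) {
    # 5'->3' nucleotide order for this strand
    ord <- if (strand == 1) 0:(N - 1) else (N - 1):0
    S <- .site_index(sites, strand, ord, "S")
    P <- .site_index(sites, strand, ord, "P")
    B <- .site_index(sites, strand, ord, "B")
    k  <- seq_len(N)        # 1-based position along the strand
    im <- seq_len(N - 1)    # positions with a 3' neighbour
    bonds[[length(bonds) + 1]] <- data.frame(
      i = c(S,            S[im],     P[-1],     B[im]),
      j = c(B,            P[im + 1], S[-1],     B[im + 1]),
      class = rep(c("SB", "SP", "PS", "BB"), c(N, N - 1, N - 1, N - 1)))
    if (N >= 2) {
      angles[[length(angles) + 1]] <- data.frame(
        i = c(S[im],      P[-1],  P[im + 1]),
        j = c(P[im + 1],  S[-1],  S[im]),
        k = c(S[im + 1],  B[-1],  B[im]),
        class = rep(c("SPS", "5PSB3", "3PSB5"), each = N - 1))
    }
    if (N >= 3) {
      i3 <- seq_len(N - 2)  # positions with two 3' neighbours
      dihedrals[[length(dihedrals) + 1]] <- data.frame(
        i = c(S[i3],      P[i3 + 1],  S[im],     B[im],     P[im + 1], P[-1]),
        j = c(P[i3 + 1],  S[i3 + 1],  P[im + 1], S[im],     S[im],     S[-1]),
        k = c(S[i3 + 1],  P[i3 + 2],  S[im + 1], P[im + 1], B[im],     B[-1]),
        l = c(P[i3 + 2],  S[i3 + 2],  B[im + 1], S[im + 1], B[im + 1], B[-N]),
        class = rep(c("SPSP", "PSPS", "SPSB53", "SPSB35", "PSBB53", "PSBB35"),
                    c(N - 2, N - 2, N - 1, N - 1, N - 1, N - 1)))
    }
  }
  rbind0 <- function(l) { d <- do.call(rbind, l); rownames(d) <- NULL; d }
  structure(list(bonds = rbind0(bonds), angles = rbind0(angles),
                 dihedrals = rbind0(dihedrals), closed = FALSE),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology (%s): %d bonds, %d angles, %d dihedrals\n",
              if (x$closed) "closed" else "open",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  invisible(x)
}

#' Close the covalent topology of a circularized duplex
#'
#' Adds the bonded terms that join the two strand termini of an N-bp
#' circle: per strand three bonds (`SP`, `PS`, `BB`), three angles
#' (`SPS`, `5PSB3`, `3PSB5`) and eight dihedrals (two `SPSP`, two `PSPS`,
#' one each of `SPSB53`, `SPSB35`, `PSBB53`, `PSBB35`) -- 6 bonds, 6
#' angles and 16 dihedrals in total, independent of N.
#'
#' @param topo an open `topology` from [build_topology()].
#' @param conf the companion (circularized) `conformation`; used to
#'   resolve terminal site ids.
#' @return the closed `topology` (`closed = TRUE`).
#' @export
close_topology <- function(topo, conf) {
  stopifnot(inherits(topo, "topology"), inherits(conf, "conformation"))
  if (isTRUE(topo$closed))
    .stopf("topology is already closed; close_topology is not idempotent by design")
  N <- attr(conf, "N")
  if (N < 3) .stopf("closure requires N >= 3")
  sites <- conf$sites
  for (strand in 1:2) {
    ord <- if (strand == 1) 0:(N - 1) else (N - 1):0
    S <- .site_index(sites, strand, ord, "S")
    P <- .site_index(sites, strand, ord, "P")
    B <- .site_index(sites, strand, ord, "B")
    # seam between strand position N (3' end) and position 1 (5' end)
    topo$bonds <- rbind(topo$bonds, data.frame(
      i = c(S[N], P[1], B[N]),
      j = c(P[1], S[1], B[1]),
      class = c("SP", "PS", "BB")))
    topo$angles <- rbind(topo$angles, data.frame(
      i = c(S[N], P[1], P[1]),
      j = c(P[1], S[1], S[N]),
      k = c(S[1], B[1], B[N]),
      class = c("SPS", "5PSB3", "3PSB5")))
    topo$dihedrals <- rbind(topo$dihedrals, data.frame(
      i = c(S[N - 1], S[N], P[N], P[1], S[N], B[N], P[1], P[1]),
      j = c(P[N],     P[1], S[N], S[1], P[1], S[N], S[1], S[N]),
      k = c(S[N],     S[1], P[1], P[2], S[1], P[1], B[1], B[N]),
      l = c(P[1],     P[2], S[1], S[2], B[1], S[1], B[N], B[1]),
      class = c("SPSP", "SPSP", "PSPS", "PSPS",
                "SPSB53", "SPSB35", "PSBB35", "PSBB53")))
  }
  rownames(topo$bonds) <- rownames(topo$angles) <- rownames(topo$dihedrals) <- NULL
  topo$closed <- TRUE
  topo
}
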