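#' Write a conformation (and topology) to a standard geometry format
#'
#' Supported formats: `"xyz"` (element column = S/P/B tag, coordinates to
#' 1e-4 Angstrom), `"pdb"` (coarse-grained beads as HETATM records, chain
#' A/B for the two strands, written with \pkg{bio3d}) and `"lammps-data"`
#' (molecular-style data file with Atoms, Bonds, Angles and Dihedrals
#' sections; class labels are mapped to integer types and the mapping is
#' emitted as comment legend lines). Each format round-trips through the
#' companion [read_geometry()] to its stated precision.
#'
#' @param conf a `conformation`.
#' @param topo a `topology`; required for `"lammps-data"`, ignored
#'   otherwise.
#' @param format one of `"xyz"`, `"pdb"`, `"lammps-data"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(conf, topo = NULL,
                           format = c("xyz", "pdb", "lammps-data"), path) {
  stopifnot(inherits(conf, "conformation"))
  format <- match.arg(format)
  sites <- conf$sites
  if (format == "xyz") {
    lines <- c(
      as.character(nrow(sites)),
      sprintf("minicircle N=%d", attr(conf, "N")),
      sprintf("%s %.4f %.4f %.4f", sites$atom, sites$x, sites$y, sites$z))
    writeLines(lines, path)
  } else if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(sites[, c("x", "y", "z")]))),
      type = rep("HETATM", nrow(sites)),
      eleno = sites$site_id,
      elety = sites$atom,
      resid = paste0("D", sites$base),
      resno = sites$nt + 1L,
      chain = c("A", "B")[sites$strand])
  } else {
    if (is.null(topo)) .stopf("lammps-data output requires a topology")
    .write_lammps_data(conf, topo, path)
  }
  invisible(path)
}

.type_legend <- function(sites, topo) {
  list(
    atom = c("1 S", "1 P", "1 B", "2 S", "2 P", "2 B"),
    bond = sort(unique(topo$bonds$class)),
    angle = sort(unique(topo$angles$class)),
    dihedral = sort(unique(topo$dihedrals$class)))
}

.write_lammps_data <- function(conf, topo, path) {
  sites <- conf$sites
  leg <- .type_legend(sites, topo)
  atom_type <- match(paste(sites$strand, sites$atom), leg$atom)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file: coarse-grained DNA minicircle (N=%d bp)", attr(conf, "N"))
  w("# atom types: %s", paste(sprintf("%d=%s", seq_along(leg$atom),
                                      gsub(" ", "", leg$atom)), collapse = " "))
  w("# bond types: %s", paste(sprintf("%d=%s", seq_along(leg$bond), leg$bond),
                              collapse = " "))
  w("# angle types: %s", paste(sprintf("%d=%s", seq_along(leg$angle), leg$angle),
                               collapse = " "))
  w("# dihedral types: %s", paste(sprintf("%d=%s", seq_along(leg$dihedral),
                                          leg$dihedral), collapse = " "))
  w("")
  w("%d atoms", nrow(sites))
  w("%d bonds", nrow(topo$bonds))
  w("%d angles", nrow(topo$angles))
  w("%d dihedrals", nrow(topo$dihedrals))
  w("")
  w("%d atom types", length(leg$atom))
  w("%d bond types", length(leg$bond))
  w("%d angle types", length(leg$angle))
  w("%d dihedral types", length(leg$dihedral))
  w("")
  pad <- max(abs(c(sites$x, sites$y, sites$z))) + 10
  w("%.4f %.4f xlo xhi", -pad, pad)
  w("%.4f %.4f ylo yhi", -pad, pad)
  w("%.4f %.4f zlo zhi", -pad, pad)
  w("")
  w("Masses")
  w("")
  for (t in seq_along(leg$atom)) w("%d 1.0", t)
  w("")
  w("Atoms # molecular")
  w("")
  w("%d 1 %d %.6f %.6f %.6f", sites$site_id, atom_type,
    sites$x, sites$y, sites$z)
  w("")
  w("Bonds")
  w("")
  w("%d %d %d %d", seq_len(nrow(topo$bonds)),
    match(topo$bonds$class, leg$bond), topo$bonds$i, topo$bonds$j)
  w("")
  w("Angles")
  w("")
  w("%d %d %d %d %d", seq_len(nrow(topo$angles)),
    match(topo$angles$class, leg$angle),
    topo$angles$i, topo$angles$j, topo$angles$k)
  w("")
  w("Dihedrals")
  w("")
  w("%d %d %d %d %d %d", seq_len(nrow(topo$dihedrals)),
    match(topo$dihedrals$class, leg$dihedral),
    topo$dihedrals$i, topo$dihedrals$j, topo$dihedrals$k, topo$dihedrals$l)
}

#' Read geometry written by [write_geometry()]
#'
#' @param path input file path.
#' @param format one of `"xyz"`, `"pdb"`, `"lammps-data"`.
#' @return for `"xyz"` a data frame (`atom`, `x`, `y`, `z`); for `"pdb"`
#'   a data frame (`site_id`, `strand`, `nt`, `atom`, `x`, `y`, `z`); for
#'   `"lammps-data"` a list with `atoms` (data frame `site_id`, `type`,
#'   `x`, `y`, `z`) and counts `n_bonds`, `n_angles`, `n_dihedrals`.
#' @export
read_geometry <- function(path, format = c("xyz", "pdb", "lammps-data")) {
  format <- match.arg(format)
  if (format == "xyz") {
    n <- as.integer(readLines(path, n = 1))
    d <- utils::read.table(path, skip = 2, nrows = n,
                           col.names = c("atom", "x", "y", "z"))
    return(d)
  }
  if (format == "pdb") {
    p <- bio3d::read.pdb(path)
    a <- p$atom
    return(data.frame(site_id = a$eleno,
                      strand = match(a$chain, c("A", "B")),
                      nt = a$resno - 1L, atom = trimws(a$elety),
                      x = a$x, y = a$y, z = a$z))
  }
  lines <- readLines(path)
  counts <- function(tag) {
    ln <- grep(paste0("^\\s*\\d+\\s+", tag, "\\s*$"), lines, value = TRUE)[1]
    as.integer(sub("^\\s*(\\d+).*", "\\1", ln))
  }
  read_section <- function(name, ncol, nrows) {
    start <- grep(paste0("^", name, "\\b"), lines)[1]
    body <- lines[(start + 2):(start + 1 + nrows)]
    m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                               function(x) as.numeric(x[seq_len(ncol)])))
    m
  }
  n_atoms <- counts("atoms")
  m <- read_section("Atoms", 6, n_atoms)
  atoms <- data.frame(site_id = as.integer(m[, 1]), type = as.integer(m[, 3]),
                      x = m[, 4], y = m[, 5], z = m[, 6])
  atoms <- atoms[order(atoms$site_id), ]
  rownames(atoms) <- NULL
  list(atoms = atoms, n_bonds = counts("bonds"),
       n_angles = counts("angles"), n_dihedrals = counts("dihedrals"))
}

#' Write the site identity map of a conformation
#'
#' CSV mapping every site id to (strand, nucleotide, atom type, base),
#' used to resolve site identity when reading bare-coordinate trajectory
#' formats (XYZ, LAMMPS dump).
#'
#' @param conf a `conformation`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_map <- function(conf, path) {
  stopifnot(inherits(conf, "conformation"))
  utils::write.csv(conf$sites[, c("site_id", "strand", "nt", "atom", "base")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site identity map
#'
#' @param path CSV path written by [write_site_map()].
#' @return data frame with columns `site_id`, `strand`, `nt`, `atom`, `base`.
#' @export
read_site_map <- function(path) {
  utils::read.csv(path, colClasses = c(site_id = "integer", strand = "integer",
                                       nt = "integer", atom = "character",
                                       base = "character"))
}
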