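#' Coarse-grained minicircle trajectory container
#'
#' A `cg_trajectory` stores per-frame coordinates of all `6N` sites of a
#' minicircle as a list of `6N x 3` matrices (rows ordered by site id),
#' one time stamp per frame (ns), and a site identity table resolving each
#' row to (strand, nucleotide, atom type).
#'
#' @param frames list of numeric `6N x 3` matrices.
#' @param times numeric vector of frame times in ns, one per frame.
#' @param sites site identity data frame with columns `site_id`, `strand`,
#'   `nt`, `atom` (as produced by a `conformation` or [read_site_map()]).
#' @param N number of base pairs.
#' @return an object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(frames, times, sites, N) {
  stopifnot(is.list(frames), length(frames) == length(times))
  if (N < 8) .stopf("minicircle trajectories need N >= 8 (four well-separated phosphates)")
  nsite <- 6L * N
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == nsite &&
                 ncol(f) == 3, logical(1))
  if (!all(ok)) .stopf("every frame must be a %d x 3 coordinate matrix", nsite)
  structure(list(frames = frames, times = as.numeric(times),
                 sites = sites, N = as.integer(N)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("Minicircle trajectory: %d bp, %d frames, t = %.3g .. %.3g ns\n",
              x$N, length(x$frames),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' Extract one frame of a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param i frame number (1-based).
#' @return an object of class `cg_frame`: list with `xyz` (matrix),
#'   `sites`, `N`, `time`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (i < 1 || i > length(traj$frames)) .stopf("frame index out of range")
  structure(list(xyz = traj$frames[[i]], sites = traj$sites, N = traj$N,
                 time = traj$times[i]), class = "cg_frame")
}

#' Convert a conformation to a single-frame trajectory frame
#'
#' @param conf a `conformation` (typically circular).
#' @param time frame time stamp in ns.
#' @return a `cg_frame`.
#' @export
as_cg_frame <- function(conf, time = 0) {
  stopifnot(inherits(conf, "conformation"))
  structure(list(xyz = as.matrix(conf$sites[, c("x", "y", "z")]),
                 sites = conf$sites[, c("site_id", "strand", "nt", "atom")],
                 N = attr(conf, "N"), time = time),
            class = "cg_frame")
}

#' Write a trajectory as multi-frame XYZ
#'
#' One block per frame; the comment line carries the time stamp as
#' `t= <ns>`.
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  atom <- traj$sites$atom[order(traj$sites$site_id)]
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(c(as.character(nrow(f)), sprintf("t= %.6f", traj$times[i]),
                 sprintf("%s %.4f %.4f %.4f", atom, f[, 1], f[, 2], f[, 3])),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ trajectory path (comment lines carrying `t= <ns>`).
#' @param sites site identity table (e.g. from [read_site_map()]) mapping
#'   row order to (strand, nt, atom); row `k` of each frame is site id `k`.
#' @return a `cg_trajectory`.
#' @export
read_xyz_trajectory <- function(path, sites) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(); i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    tm <- suppressWarnings(as.numeric(sub(".*t=\\s*", "", lines[i + 1])))
    body <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    m <- matrix(as.numeric(unlist(lapply(body, `[`, 2:4))),
                ncol = 3, byrow = TRUE)
    frames[[length(frames) + 1]] <- m
    times <- c(times, if (is.na(tm)) length(times) else tm)
    i <- i + 2L + n
  }
  cg_trajectory(frames, times, sites, nrow(frames[[1]]) / 6L)
}

#' Write a trajectory in LAMMPS text dump format
#'
#' Emits `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS id type x y z`
#' blocks. Time stamps are stored as integer steps via `timestep_per_ns`.
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @param timestep_per_ns dump steps per ns (default 1000, i.e. step =
#'   time in ps).
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(traj, path, timestep_per_ns = 1000) {
  stopifnot(inherits(traj, "cg_trajectory"))
  ord <- order(traj$sites$site_id)
  type <- match(paste(traj$sites$strand, traj$sites$atom)[ord],
                c("1 S", "1 P", "1 B", "2 S", "2 P", "2 B"))
  con <- file(path, "w"); on.exit(close(con))
  pad <- max(abs(unlist(lapply(traj$frames, range)))) + 10
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(c("ITEM: TIMESTEP",
                 sprintf("%d", round(traj$times[i] * timestep_per_ns)),
                 "ITEM: NUMBER OF ATOMS",
                 as.character(nrow(f)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 rep(sprintf("%.4f %.4f", -pad, pad), 3),
                 "ITEM: ATOMS id type x y z",
                 sprintf("%d %d %.4f %.4f %.4f", seq_len(nrow(f)), type,
                         f[, 1], f[, 2], f[, 3])), con)
  }
  invisible(path)
}

#' Read a LAMMPS text dump trajectory
#'
#' Expects `ITEM: ATOMS` sections with columns `id type x y z` (any order
#' of rows; sorted by id on read).
#'
#' @param path dump file path.
#' @param sites site identity table mapping atom id to (strand, nt, atom).
#' @param timestep_per_ns dump steps per ns used to recover times
#'   (default 1000).
#' @return a `cg_trajectory`.
#' @export
read_lammps_dump <- function(path, sites, timestep_per_ns = 1000) {
  lines <- readLines(path)
  ts_at <- grep("^ITEM: TIMESTEP", lines)
  frames <- list(); times <- numeric()
  for (s in ts_at) {
    step <- as.numeric(lines[s + 1])
    n <- as.integer(lines[s + 3])
    hdr <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[s + 8]), "\\s+")[[1]]
    body <- strsplit(trimws(lines[(s + 9):(s + 8 + n)]), "\\s+")
    m <- matrix(as.numeric(unlist(body)), ncol = length(hdr), byrow = TRUE)
    colnames(m) <- hdr
    m <- m[order(m[, "id"]), , drop = FALSE]
    frames[[length(frames) + 1]] <- unname(m[, c("x", "y", "z")])
    times <- c(times, step / timestep_per_ns)
  }
  cg_trajectory(frames, times, sites, nrow(frames[[1]]) / 6L)
}
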