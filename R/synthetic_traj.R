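# Synthetic minicircle trajectories with prescribed poloidal statistics.
#
# Frames are rigid poloidal rotations of the ideal minicircle: for each
# frame an angle is drawn from a (possibly bimodal) von Mises
# distribution, all six helical angular offsets of the linear duplex are
# shifted by the corresponding rotation, and the molecule is re-bent into
# the circle. Because the poloidal-angle estimator has its own zero point
# (set by where the tracked phosphate sits relative to the body-fixed
# axes), the generator calibrates the rotation-to-measured-angle map once
# on the noiseless reference circle and inverts it, so the measured
# poloidal angle of a frame equals the drawn angle to well below 0.1
# degrees.

#' Specification of a synthetic poloidal trajectory
#'
#' @param N minicircle size in bp (default 105).
#' @param mu_deg prescribed circular mean of the poloidal angle (degrees).
#' @param kappa von Mises concentration (>= 0; 0 = uniform). Use
#'   [vonmises_kappa()] to obtain the concentration for a target circular
#'   SD.
#' @param n_frames number of frames (>= 1).
#' @param dt_ns frame spacing in ns (default 0.02, i.e. 5,000 frames per
#'   100 ns).
#' @param seed random seed.
#' @param tracked tracked nucleotide index used for calibration
#'   (default 0).
#' @param radius bend radius in Angstrom; default closes the contour.
#' @param target_twist target step twist (degrees/bp) before linking-
#'   number adjustment (default 360/10.5).
#' @param mixture optional list `list(mu2_deg =, weight2 =)` adding a
#'   second von Mises component (same kappa) with mixing weight
#'   `weight2`, for bimodal poloidal landscapes such as phased-adenine
#'   repeat sequences.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(N = 105, mu_deg = 0, kappa = 10,
                            n_frames = 1000, dt_ns = 0.02, seed = 1,
                            tracked = 0, radius = NULL,
                            target_twist = 360 / 10.5, mixture = NULL) {
  if (!.is_count(N) || N < 8) .stopf("N must be an integer >= 8")
  if (kappa < 0) .stopf("kappa must be >= 0")
  if (!.is_count(n_frames) || n_frames < 1) .stopf("n_frames must be >= 1")
  if (dt_ns <= 0) .stopf("dt_ns must be positive")
  if (!is.null(mixture) &&
      (is.null(mixture$mu2_deg) || is.null(mixture$weight2) ||
       mixture$weight2 < 0 || mixture$weight2 > 1))
    .stopf("mixture must be list(mu2_deg =, weight2 in [0,1])")
  structure(list(N = N, mu_deg = mu_deg, kappa = kappa, n_frames = n_frames,
                 dt_ns = dt_ns, seed = seed, tracked = tracked,
                 radius = radius, target_twist = target_twist,
                 mixture = mixture),
            class = "trajectory_spec")
}

# per-site constants of the ideal circle in site-id order, plus a
# function mapping a poloidal rotation (deg) to a 6N x 3 frame matrix
.circle_generator <- function(spec, params = default_helix_parameters()) {
  ct <- choose_circle_twist(spec$N, spec$target_twist)
  params <- helix_parameters(params$table, twist = ct$twist, rise = params$rise)
  seqN <- substr(strrep("ACGT", ceiling(spec$N / 4)), 1, spec$N)
  lin <- build_linear_helix(params, spec$N, seqN)
  s <- lin$sites
  key <- paste(s$strand, s$atom)
  tab <- params$table
  tkey <- paste(tab$strand, tab$atom)
  r <- tab$r[match(key, tkey)]
  th0 <- tab$theta0[match(key, tkey)]
  z0 <- tab$z0[match(key, tkey)]
  nt <- s$nt
  R <- if (is.null(spec$radius)) spec$N * params$rise / (2 * pi) else spec$radius
  frame_at <- function(beta) {
    ang <- (nt * ct$twist + th0 + beta) * DEG2RAD
    x <- r * cos(ang); y <- r * sin(ang); z <- nt * params$rise + z0
    x <- x - mean(x); y <- y - mean(y) + R; z <- z - mean(z)
    cbind(x, y * cos(z / R), y * sin(z / R), deparse.level = 0)
  }
  sites <- s[, c("site_id", "strand", "nt", "atom")]
  idx <- .poloidal_index(sites, spec$N, spec$tracked)
  # calibration: measured poloidal angle as a function of the applied
  # rotation, on a 1-degree grid, unwrapped to a monotone curve
  grid <- seq(0, 360, by = 1)
  g <- vapply(grid, function(b) .poloidal_core(frame_at(b), idx)$phi,
              numeric(1))
  d <- wrap_angle(diff(g))
  gu <- g[1] + cumsum(c(0, d))
  increasing <- gu[length(gu)] > gu[1]
  beta_for <- function(phi_target) {
    t <- gu[1] + (if (increasing) (phi_target - gu[1]) %% 360
                  else -((gu[1] - phi_target) %% 360))
    if (increasing) stats::approx(gu, grid, xout = t)$y
    else stats::approx(rev(gu), rev(grid), xout = t)$y
  }
  list(frame_at = frame_at, beta_for = beta_for, sites = sites,
       params = params, twist = ct$twist, Lk = ct$Lk, radius = R)
}

#' Generate a synthetic minicircle trajectory with known poloidal truth
#'
#' Draws one poloidal angle per frame from the von Mises distribution of
#' the spec (or a two-component mixture), applies the corresponding rigid
#' poloidal rotation to the ideal minicircle, and returns the frames
#' together with the drawn ground-truth angles. Identical specs and seeds
#' give bit-identical output. The model emulates the equilibrium
#' fluctuations of a minicircle with a narrowly distributed poloidal
#' orientation; it contains no bending or twist deformations beyond the
#' rigid rotation.
#'
#' @param spec a [trajectory_spec()].
#' @param params base helical parameters (default
#'   [default_helix_parameters()]).
#' @return list with `trajectory` (a `cg_trajectory`, frame times
#'   `dt_ns, 2 dt_ns, ...`), `truth_deg` (drawn poloidal angles, wrapped
#'   to (-180, 180]) and `spec`.
#' @export
make_poloidal_trajectory <- function(spec, params = default_helix_parameters()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  gen <- .circle_generator(spec, params)
  phi <- .with_seed(spec$seed, {
    if (is.null(spec$mixture)) {
      rvonmises(spec$n_frames, spec$mu_deg, spec$kappa)
    } else {
      pick2 <- stats::runif(spec$n_frames) < spec$mixture$weight2
      out <- numeric(spec$n_frames)
      out[!pick2] <- rvonmises(sum(!pick2), spec$mu_deg, spec$kappa)
      out[pick2] <- rvonmises(sum(pick2), spec$mixture$mu2_deg, spec$kappa)
      out
    }
  })
  beta <- gen$beta_for(phi)
  frames <- lapply(beta, gen$frame_at)
  traj <- cg_trajectory(frames, seq_len(spec$n_frames) * spec$dt_ns,
                        gen$sites, spec$N)
  list(trajectory = traj, truth_deg = phi, spec = spec)
}
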