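# Circular statistics for poloidal-angle distributions.

#' Circular mean and standard deviation of a set of angles
#'
#' Standard directional statistics: with unit vectors
#' `(cos(theta), sin(theta))`, the mean resultant length is
#' `Rbar = |mean vector|`, the circular mean is the direction of the mean
#' vector, and the circular standard deviation is
#' `sqrt(-2 log(Rbar))` (radians), reported in degrees.
#'
#' @param angles numeric vector of angles in degrees (at least 2).
#' @return object of class `circular_summary`: list with `mu_deg`
#'   (mean, in (-180, 180]), `sd_deg`, `rbar`, `n`.
#' @examples
#' circular_mean_sd(c(10, 350))  # mean 0, rbar = cos(10 deg)
#' @export
circular_mean_sd <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) < 2) .stopf("need at least 2 angles")
  th <- angles * DEG2RAD
  cm <- mean(cos(th)); sm <- mean(sin(th))
  rbar <- sqrt(cm^2 + sm^2)
  if (rbar < 1e-12)
    .stopf("undefined circular mean: resultant length is (numerically) zero")
  structure(list(mu_deg = wrap_angle(atan2(sm, cm) * RAD2DEG),
                 sd_deg = sqrt(-2 * log(min(rbar, 1))) * RAD2DEG,
                 rbar = rbar, n = length(angles)),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("Circular summary: mean %.2f deg, SD %.2f deg, Rbar %.4f, n = %d\n",
              x$mu_deg, x$sd_deg, x$rbar, x$n))
  invisible(x)
}

#' Mean-centred histogram of a poloidal series
#'
#' Subtracts the circular mean from all angles (equivalently, rotates the
#' distribution by the negative mean), wraps to (-180, 180] and bins.
#' Counts sum to the sample size; the centred series has circular mean 0.
#'
#' @param series a `poloidal_series` (column `phi_deg`) or a numeric
#'   vector of angles in degrees.
#' @param bins number of equal-width bins over (-180, 180] (default 72,
#'   i.e. 5-degree bins).
#' @return list with `breaks` (degrees, length `bins + 1`), `counts`,
#'   `mids` and `mu_deg` (the subtracted mean).
#' @export
mean_centered_histogram <- function(series, bins = 72) {
  angles <- if (is.data.frame(series)) series$phi_deg else series
  if (!length(angles)) .stopf("empty series")
  mu <- circular_mean_sd(angles)$mu_deg
  centred <- wrap_angle(angles - mu)
  breaks <- seq(-180, 180, length.out = bins + 1)
  # wrap_angle returns (-180, 180]; hist() bins (lo, hi] with right = TRUE
  # except the first bin which is closed; -180 never occurs, so counts
  # partition the sample exactly
  h <- graphics::hist(centred, breaks = breaks, plot = FALSE, right = TRUE)
  list(breaks = breaks, counts = h$counts, mids = h$mids, mu_deg = mu)
}

#' Draw samples from a von Mises distribution
#'
#' Best-Fisher rejection sampler for the circular normal distribution
#' with mean direction `mu` (degrees) and concentration `kappa`.
#' `kappa = 0` gives the uniform circular distribution.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter (>= 0).
#' @return numeric vector of angles in degrees, wrapped to (-180, 180].
#' @references Best, D.J. and Fisher, N.I. (1979) Efficient simulation of
#'   the von Mises distribution. Applied Statistics 28, 152-157.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) .stopf("kappa must be non-negative")
  if (kappa == 0) return(wrap_angle(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(length(th), m)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_angle(mu + out * RAD2DEG)
}

# ratio I1(kappa)/I0(kappa), stable for large kappa
.vm_a1 <- function(kappa) {
  if (kappa == 0) return(0)
  if (kappa < 1e4)
    return(besselI(kappa, 1, expon.scaled = TRUE) /
             besselI(kappa, 0, expon.scaled = TRUE))
  # asymptotic expansion for large concentration
  1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3)
}

#' Population circular SD of a von Mises distribution
#'
#' Closed form: the mean resultant length of von Mises(`kappa`) is
#' `I1(kappa)/I0(kappa)`, so the circular SD is
#' `sqrt(-2 log(I1/I0))`, returned in degrees.
#'
#' @param kappa concentration parameter (> 0).
#' @return circular standard deviation in degrees.
#' @export
vonmises_sd <- function(kappa) {
  if (kappa <= 0) .stopf("kappa must be positive")
  sqrt(-2 * log(.vm_a1(kappa))) * RAD2DEG
}

#' Concentration giving a target von Mises circular SD
#'
#' Numerically inverts [vonmises_sd()].
#'
#' @param sd_deg target circular standard deviation in degrees (> 0).
#' @return concentration `kappa`.
#' @export
vonmises_kappa <- function(sd_deg) {
  if (sd_deg <= 0) .stopf("sd_deg must be positive")
  stats::uniroot(function(k) vonmises_sd(k) - sd_deg,
                 lower = 1e-6, upper = 1e8, tol = 1e-10)$root
}
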