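# Fixed-period sinusoidal phasing of insert-position series.

#' Insert-position summary series
#'
#' Per-insert-position central values (e.g. median AFM offset distance in
#' nm, or mean inverted horizontal displacement in Angstrom) with their
#' spreads, used as input to [fit_fixed_period_sinusoid()].
#'
#' @param position_bp insert positions in bp, strictly increasing.
#' @param value central value per position.
#' @param sd per-position spread (standard deviation, same units as
#'   `value`); must be positive wherever used as a weight. Optional.
#' @param label series label.
#' @return data frame of class `position_series`.
#' @export
position_series <- function(position_bp, value, sd = NULL, label = "") {
  if (is.unsorted(position_bp, strictly = TRUE))
    .stopf("positions must be strictly increasing")
  if (length(value) != length(position_bp))
    .stopf("value and position_bp lengths differ")
  out <- data.frame(position_bp = position_bp, value = value,
                    sd = if (is.null(sd)) NA_real_ else sd,
                    label = label)
  class(out) <- c("position_series", "data.frame")
  out
}

#' Read / write position series CSV
#'
#' Columns `position_bp`, `value`, `sd`, `label`; a file may hold several
#' labelled series.
#'
#' @param path CSV path.
#' @return a `position_series` data frame (reader); `path` invisibly
#'   (writer).
#' @export
read_position_series <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("position_series", "data.frame")
  out
}

#' @rdname read_position_series
#' @param series a `position_series`.
#' @export
write_position_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a fixed-period sinusoid to an insert-position series
#'
#' Fits `value = A cos(2 pi (p - p0) / T) + C` with the period `T` held
#' fixed (default 10.5 bp, the B-DNA helical repeat). The fit is solved by
#' the exact linear reparameterization
#' `value = a cos(2 pi p / T) + b sin(2 pi p / T) + C` (weighted linear
#' least squares via [stats::lm()]), then `A = sqrt(a^2 + b^2)` and
#' `p0 = (T / 2 pi) atan2(b, a) mod T` -- deterministic, with no starting
#' point. Weighting is by inverse variance (`1/sd^2`) by default;
#' `weighting = "inverse-sd"` uses `1/sd`, `"none"` is unweighted.
#'
#' @param series a `position_series` (or data frame with columns
#'   `position_bp`, `value` and, for weighted fits, `sd`); at least 4
#'   positions.
#' @param period fixed period in bp (default 10.5).
#' @param weighting `"inverse-variance"` (default), `"inverse-sd"` or
#'   `"none"`.
#' @return object of class `sine_fit`: list with `amplitude` (>= 0),
#'   `peak_bp` (peak position mod `period`, in `[0, period)`), `offset`,
#'   `period`, `wrss` (weighted residual sum of squares), `fitted`.
#' @examples
#' p <- seq(0, 12, 2)
#' s <- position_series(p, 2 * cos(2 * pi * (p - 1.3) / 10.5) + 3)
#' fit_fixed_period_sinusoid(s, weighting = "none")
#' @export
fit_fixed_period_sinusoid <- function(series, period = 10.5,
                                      weighting = c("inverse-variance",
                                                    "inverse-sd", "none")) {
  weighting <- match.arg(weighting)
  p <- series$position_bp
  v <- series$value
  if (length(p) < 4)
    .stopf("underdetermined fit: need at least 4 positions, got %d", length(p))
  w <- switch(weighting,
    "inverse-variance" = 1 / series$sd^2,
    "inverse-sd" = 1 / series$sd,
    "none" = rep(1, length(p)))
  if (weighting != "none" && (anyNA(w) || any(!is.finite(w))))
    .stopf("degenerate weights: zero or missing spread with weighting enabled")
  om <- 2 * pi / period
  cx <- cos(om * p); sx <- sin(om * p)
  fit <- stats::lm(v ~ cx + sx, weights = w)
  co <- stats::coef(fit)
  a <- co[["cx"]]; b <- co[["sx"]]; C <- co[["(Intercept)"]]
  A <- sqrt(a^2 + b^2)
  p0 <- (atan2(b, a) / om) %% period
  structure(list(amplitude = A, peak_bp = p0, offset = C, period = period,
                 wrss = sum(w * stats::residuals(fit)^2),
                 fitted = stats::fitted(fit)),
            class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf("Fixed-period sinusoid fit (T = %g bp): A = %.4g, peak at %.2f bp, offset %.4g\n",
              x$period, x$amplitude, x$peak_bp, x$offset))
  invisible(x)
}

#' Phase lag between two fixed-period sinusoid fits
#'
#' The lag of series b behind series a: `(peak_b - peak_a) mod T`,
#' reported in `[0, T)` bp and as `lag / T * 360` degrees. The display
#' value rounds the degrees to the nearest integer (e.g. a 5.5-bp lag at
#' T = 10.5 is 188.57 degrees, displayed as 189).
#'
#' @param fit_a,fit_b `sine_fit` objects with equal periods.
#' @return list with `lag_bp`, `lag_deg` and `lag_deg_display`.
#' @export
phase_lag <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "sine_fit"), inherits(fit_b, "sine_fit"))
  if (!isTRUE(all.equal(fit_a$period, fit_b$period)))
    .stopf("incompatible fits: periods differ (%g vs %g)",
           fit_a$period, fit_b$period)
  T <- fit_a$period
  lag_bp <- (fit_b$peak_bp - fit_a$peak_bp) %% T
  lag_deg <- lag_bp / T * 360
  list(lag_bp = lag_bp, lag_deg = lag_deg,
       lag_deg_display = round(lag_deg))
}

#' Poloidal rotation angle left invariant by a repeat sequence
#'
#' A perfectly circular duplex whose sequence repeats every
#' `repeat_unit_bp` base pairs is invariant under a poloidal rotation by
#' `repeat_unit_bp * 360 / h` degrees, where `h` is the helical period in
#' bp per turn: rotating the circle by one repeat unit of twist maps the
#' sequence onto itself. For a homopolymer (repeat unit 1 bp) at
#' h = 10.5 this is ~34.3 degrees; for a dinucleotide repeat ~68.6
#' degrees. Distributions constrained by such symmetry repeat at this
#' angle and, for small angles, blur toward uniformity.
#'
#' @param repeat_unit_bp sequence repeat unit in bp (>= 1).
#' @param h helical period in bp per turn (default 10.5).
#' @return rotation angle in degrees.
#' @examples
#' rotational_symmetry_angle(1)   # poly-A:   ~34.3 deg
#' rotational_symmetry_angle(2)   # poly-(GC): ~68.6 deg
#' @export
rotational_symmetry_angle <- function(repeat_unit_bp, h = 10.5) {
  if (!.is_count(repeat_unit_bp) || repeat_unit_bp < 1)
    .stopf("repeat_unit_bp must be a positive integer")
  if (h <= 0) .stopf("h must be positive")
  repeat_unit_bp * 360 / h
}
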