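# Internal helpers shared across modules.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap angles into the interval (-180, 180]
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 360, 180))
#' @export
wrap_angle <- function(theta) {
  w <- theta - 360 * floor(theta / 360 + 0.5)
  # floor-based wrap lands on [-180, 180); move -180 to +180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

# unit vector; errors on near-zero input
.unit <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate ", what, ": zero length", call. = FALSE)
  v / n
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# evaluate expr with a local RNG state seeded by `seed`; the caller's
# global random state is untouched
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

.validate_sequence <- function(sequence, N) {
  if (!is.character(sequence) || length(sequence) != 1L)
    .stopf("`sequence` must be a single character string")
  if (nchar(sequence) != N)
    .stopf("sequence length (%d) does not match N (%d)", nchar(sequence), N)
  if (grepl("[^ACGT]", sequence))
    .stopf("invalid sequence: only A, C, G, T are allowed")
  invisible(sequence)
}

# reverse complement via Biostrings; returns plain character
.revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

.complement <- function(sequence) {
  as.character(Biostrings::complement(Biostrings::DNAString(sequence)))
}
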