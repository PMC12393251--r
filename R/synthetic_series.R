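# Synthetic insert-position series and minicircle sequence sets.

#' Generate a noisy insert-position series with known sinusoidal truth
#'
#' Per-position replicate values are
#' `A cos(2 pi (p - peak_bp) / period) + offset + noise`; the series
#' reports the replicate mean and SD per position. With `noise_sd = 0`
#' the values are exact and the reported spread is set to 1 (uniform
#' weights), since a zero spread would make inverse-variance weighting
#' degenerate.
#'
#' @param positions insert positions in bp (default `seq(0, 12, 2)`, the
#'   seven-construct design of a 105-bp minicircle series).
#' @param amplitude,peak_bp,offset true sinusoid parameters.
#' @param noise_sd replicate noise SD (same units as `amplitude`).
#' @param n_replicates replicates per position (default 25).
#' @param period fixed period in bp (default 10.5).
#' @param seed random seed.
#' @param label series label.
#' @return list with `series` (a [position_series()]) and `truth`
#'   (list of the generating parameters).
#' @export
make_position_series <- function(positions = seq(0, 12, 2), amplitude = 1,
                                 peak_bp = 0, offset = 0, noise_sd = 0,
                                 n_replicates = 25, period = 10.5, seed = 1,
                                 label = "synthetic") {
  if (anyDuplicated(positions)) .stopf("positions must be distinct")
  if (n_replicates < 1) .stopf("n_replicates must be >= 1")
  mu <- amplitude * cos(2 * pi * (positions - peak_bp) / period) + offset
  if (noise_sd == 0) {
    ser <- position_series(positions, mu, sd = rep(1, length(positions)),
                           label = label)
  } else {
    vals <- .with_seed(seed, {
      reps <- matrix(stats::rnorm(length(positions) * n_replicates, 0,
                                  noise_sd),
                     nrow = length(positions)) + mu
      list(mean = rowMeans(reps),
           sd = apply(reps, 1, stats::sd))
    })
    sdv <- if (n_replicates > 1) vals$sd else rep(noise_sd, length(positions))
    ser <- position_series(positions, vals$mean, sd = sdv, label = label)
  }
  list(series = ser,
       truth = list(amplitude = amplitude, peak_bp = peak_bp %% period,
                    offset = offset, period = period, noise_sd = noise_sd))
}

#' Generate a biotin-insert minicircle sequence series
#'
#' Emulates the construct design used to map poloidal orientation: a
#' fixed random core sequence plus a fixed random insert carrying a
#' marked deoxythymidine (the biotinylated dT), with the insert placed
#' after `p` core nucleotides for each requested position `p`. All
#' constructs have length `core_length + insert_length` (105 nt by
#' default), share the core as a circular subsequence, and the 0-based
#' index of the marked dT shifts by exactly the position step between
#' consecutive constructs. The generated sequences are random stand-ins,
#' not any experimentally used construct.
#'
#' @param core_length core length in nt (default 85).
#' @param insert_length insert length in nt (default 20).
#' @param positions insert positions in nt (default `seq(0, 12, 2)`).
#' @param seed random seed for the core and insert sequences.
#' @param dt_offset 0-based offset of the marked dT within the insert
#'   (default 10, near the insert midpoint).
#' @return data frame with columns `label`, `insert_position`,
#'   `sequence`, `tracked_nt` (0-based index of the marked dT in the
#'   full sequence).
#' @export
make_sequence_series <- function(core_length = 85, insert_length = 20,
                                 positions = seq(0, 12, 2), seed = 1,
                                 dt_offset = 10) {
  if (dt_offset < 0 || dt_offset >= insert_length)
    .stopf("dt_offset must lie within the insert")
  if (any(positions < 0 | positions > core_length))
    .stopf("insert positions must lie within the core")
  parts <- .with_seed(seed, {
    core <- paste(sample(c("A", "C", "G", "T"), core_length, TRUE),
                  collapse = "")
    ins <- sample(c("A", "C", "G", "T"), insert_length, TRUE)
    ins[dt_offset + 1] <- "T"   # the biotin-modified dT
    list(core = core, insert = paste(ins, collapse = ""))
  })
  out <- lapply(positions, function(p) {
    data.frame(
      label = sprintf("pos_%d", p), insert_position = p,
      sequence = paste0(substr(parts$core, 1, p), parts$insert,
                        substr(parts$core, p + 1, core_length)),
      tracked_nt = p + dt_offset)
  })
  out <- do.call(rbind, out)
  attr(out, "core") <- parts$core
  attr(out, "insert") <- parts$insert
  out
}

#' Write a sequence series as FASTA
#'
#' @param series data frame from [make_sequence_series()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sequence_series <- function(series, path) {
  set <- Biostrings::DNAStringSet(series$sequence)
  names(set) <- sprintf("%s tracked_nt=%d", series$label, series$tracked_nt)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
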