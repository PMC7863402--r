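#' Quality and length filtering of reads
#'
#' Keeps reads whose mean per-base error probability (from the phred scores)
#' is at most `max_error_rate`, and — when a target length is given — whose
#' length lies within `target_length` plus or minus `length_window`. Input
#' order is preserved. The kept/dropped counts are attached as the
#' `"filter_summary"` attribute and reported with a message.
#'
#' @param reads Read tibble from [read_fastq()].
#' @param max_error_rate Maximum mean error probability (default 0.10).
#' @param target_length,length_window Optional length filter: keep reads with
#'   `abs(length - target_length) <= length_window`. `length_window` requires
#'   `target_length`.
#' @return The filtered read tibble.
#' @export
filter_reads <- function(reads, max_error_rate = 0.10, target_length = NULL,
                         length_window = NULL) {
  stopifnot(max_error_rate > 0, max_error_rate <= 1)
  if (!is.null(length_window) && is.null(target_length)) {
    abort("length_window requires target_length")
  }
  keep <- rep(TRUE, nrow(reads))
  if (nrow(reads) > 0) {
    err <- map_dbl(reads$qual, mean_error_rate)
    keep <- err <= max_error_rate
    if (!is.null(target_length)) {
      win <- length_window %||% 0
      keep <- keep & abs(nchar(reads$seq) - target_length) <= win
    }
  }
  out <- reads[keep, , drop = FALSE]
  attr(out, "filter_summary") <- list(kept = sum(keep), dropped = sum(!keep))
  if (nrow(out) == 0 && nrow(reads) > 0) {
    warn("filter_reads: no reads passed the filters")
  }
  out
}

#' Seeded uniform subsampling of reads
#'
#' Draws exactly `n` reads uniformly without replacement, keeping the original
#' relative order. `n = 0` (the default pipeline setting) or `n` at least the
#' number of reads returns the input unchanged. The draw is fully determined
#' by `seed` and does not disturb the caller's RNG state.
#'
#' @param reads Read tibble.
#' @param n Number of reads to keep; 0 means no subsampling.
#' @param seed Integer seed (default 1234).
#' @return The subsampled read tibble.
#' @export
subsample_reads <- function(reads, n, seed = 1234) {
  stopifnot(n >= 0)
  if (n == 0 || n >= nrow(reads)) return(reads)
  idx <- withr::with_seed(seed, sort(sample.int(nrow(reads), n)))
  reads[idx, , drop = FALSE]
}
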