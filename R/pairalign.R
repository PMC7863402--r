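#' Pairwise alignment with the accuracy metric used throughout the pipeline
#'
#' Optimal affine-gap dynamic programming (Gotoh) between two sequences.
#' `alignment_length` counts every traced column including internal gaps; in
#' semi-global mode terminal gaps of either sequence are unpenalized and
#' excluded from it (BLAST-style identity over the aligned span). Identity is
#' matches over the alignment length, which in semi-global mode is extended
#' by the unaligned remainder of the better-covered sequence: for
#' near-full-length overlaps this is exactly matches/alignment_length, while
#' a few-base corner overlap between unrelated sequences scores near 0
#' instead of a spurious 1. Tie-breaking is deterministic: match over
#' mismatch over deletion over insertion.
#'
#' @param a,b Non-empty DNA strings; `a` is the reference for CIGAR purposes.
#' @param params [align_params()].
#' @param mode `"semi-global"` (default), `"global"`, or `"local"`.
#' @return A one-row tibble: `score`, `identity`, `matches`,
#'   `alignment_length`, `orientation` (always `"forward"` here), `cigar`,
#'   and the 0-based half-open aligned spans `ref_start`, `ref_end`,
#'   `query_start`, `query_end`.
#' @examples
#' align_pair("ACGTT", "ACGAT", mode = "global")  # identity 0.8
#' @export
align_pair <- function(a, b, params = align_params(),
                       mode = c("semi-global", "global", "local")) {
  mode <- match.arg(mode)
  if (length(a) != 1 || length(b) != 1 || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b)) {
    abort("align_pair: sequences must be single non-empty strings")
  }
  mcode <- c("global" = 0L, "semi-global" = 1L, "local" = 2L)[[mode]]
  r <- .align_pair_cpp(a, b, params$match, params$mismatch,
                       params$gap_open, params$gap_extend, mcode)
  denom <- r$alignment_length
  if (mode == "semi-global") {
    # dovetail-aware identity: extend the denominator by the unaligned
    # remainder of the better-covered sequence so that negligible corner
    # overlaps between unrelated sequences never look like duplicates; for
    # near-full-length overlaps this coincides with matches/alignment_length
    uncov_a <- nchar(a) - (r$ref_end - r$ref_start)
    uncov_b <- nchar(b) - (r$query_end - r$query_start)
    denom <- denom + min(uncov_a, uncov_b)
  }
  tibble(
    score = r$score,
    identity = if (denom > 0) r$matches / denom else 0,
    matches = r$matches,
    alignment_length = r$alignment_length,
    orientation = "forward",
    cigar = r$cigar,
    ref_start = r$ref_start, ref_end = r$ref_end,
    query_start = r$query_start, query_end = r$query_end
  )
}

#' Best-strand pairwise identity
#'
#' Aligns `a` against `b` and against `reverse_complement(b)` in semi-global
#' mode and returns the higher-identity result, with `orientation` recording
#' which strand of `b` was used (forward wins ties).
#'
#' @param a,b Non-empty DNA strings.
#' @param params [align_params()].
#' @return A one-row tibble as in [align_pair()].
#' @export
best_orientation_identity <- function(a, b, params = align_params()) {
  fwd <- align_pair(a, b, params, mode = "semi-global")
  rev <- align_pair(a, reverse_complement(b), params, mode = "semi-global")
  if (rev$identity > fwd$identity) {
    rev$orientation <- "reverse_complement"
    rev
  } else {
    fwd
  }
}
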