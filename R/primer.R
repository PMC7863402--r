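#' Read primer sequences from a FASTA file
#'
#' Primers may contain IUPAC ambiguity codes (common in universal barcode
#' primers); `U` is normalized to `T` on load.
#'
#' @param path FASTA file of primer sequences.
#' @return A tibble with columns `name` and `seq`.
#' @export
read_primers <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) > 0 && !hdr[1]) abort("malformed primer FASTA: no leading '>' header")
  idx <- cumsum(hdr)
  names <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(seq_along(names), function(i) {
    paste(lines[!hdr & idx == i], collapse = "")
  }, character(1))
  seqs <- chartr("U", "T", toupper(seqs))
  if (any(!nzchar(seqs))) abort("primer FASTA contains an empty sequence")
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) abort(sprintf("primer '%s' contains non-IUPAC characters", names[bad][1]))
  tibble(name = names, seq = seqs)
}

#' Does a consensus base satisfy an IUPAC primer code?
#'
#' `TRUE` iff the base belongs to the code's expansion. An `N` in the
#' consensus matches every code (permissive, so masked bases never block
#' primer detection).
#'
#' @param a A base in `{A, C, G, T, N}`.
#' @param b A single IUPAC nucleotide code.
#' @return Logical scalar.
#' @examples
#' iupac_match("A", "R")  # TRUE
#' iupac_match("C", "R")  # FALSE
#' @export
iupac_match <- function(a, b) {
  .iupac_match_cpp(toupper(a), toupper(b))
}

# best approximate occurrence of `pattern` (IUPAC) in `text`, primer-global /
# text-local with unit edit costs; positions 0-based half-open within text
primer_fit <- function(text, pattern) {
  .primer_fit_cpp(text, pattern)
}

#' Find the best primer hit near either end of a consensus
#'
#' The forward and reverse-complement of the primer are searched within a
#' window at each end of the consensus by primer-global dynamic programming
#' with unit edit costs and IUPAC-aware matching. A hit is reported when its
#' edit count is at most `ceiling(max_edit_fraction * primer length)`. Ties
#' prefer the 5' end over the 3' end, forward over reverse-complement, then
#' the leftmost position.
#'
#' @param consensus Non-empty consensus string.
#' @param primer_seq Primer sequence (IUPAC allowed).
#' @param primer_name Name carried into the hit record.
#' @param window Window length searched at each end (default 150).
#' @param max_edit_fraction Edit tolerance as a fraction of primer length
#'   (default 0.20).
#' @return A one-row tibble (`primer_name`, `strand`, `start`, `end`,
#'   `edits`, `consensus_end`) or `NULL` if no acceptable hit. Coordinates
#'   are 0-based half-open on the consensus.
#' @export
find_primer <- function(consensus, primer_seq, primer_name = "primer",
                        window = 150, max_edit_fraction = 0.20) {
  stopifnot(nzchar(consensus), max_edit_fraction >= 0, max_edit_fraction < 0.5)
  plen <- nchar(primer_seq)
  if (window < plen) {
    warn("find_primer: search window shorter than the primer; no hit reported")
    return(NULL)
  }
  len <- nchar(consensus)
  wlen <- min(window, len)
  allow <- ceiling(max_edit_fraction * plen)
  five <- substr(consensus, 1, wlen)
  three <- substr(consensus, len - wlen + 1, len)
  off3 <- len - wlen
  variants <- list(
    list(end = "5prime", strand = "forward", text = five, off = 0L, pat = primer_seq),
    list(end = "5prime", strand = "reverse_complement", text = five, off = 0L,
         pat = reverse_complement(primer_seq)),
    list(end = "3prime", strand = "forward", text = three, off = off3, pat = primer_seq),
    list(end = "3prime", strand = "reverse_complement", text = three, off = off3,
         pat = reverse_complement(primer_seq))
  )
  best <- NULL
  for (v in variants) {
    f <- primer_fit(v$text, v$pat)
    if (f$edits > allow) next
    if (is.null(best) || f$edits < best$edits) {
      best <- tibble(
        primer_name = primer_name, strand = v$strand,
        start = f$start + v$off, end = f$end + v$off, edits = f$edits,
        consensus_end = v$end
      )
    }
  }
  best
}

#' Detect and trim primers at both ends of a consensus
#'
#' The best hit per end across all primers (fewest edits; ties prefer
#' forward strand, leftmost position, then primer order) is trimmed: a 5'
#' hit is cut at its end coordinate and a 3' hit at its start coordinate,
#' returning the inner sequence. An end whose trim would leave fewer than 50
#' bases is skipped with a warning.
#'
#' @param consensus Non-empty consensus string.
#' @param primers Primer tibble from [read_primers()] (columns `name`,
#'   `seq`); may be empty.
#' @param window,max_edit_fraction As in [find_primer()].
#' @return A list with `trimmed` (string) and `hits` (tibble of the hits
#'   actually used, zero rows when none).
#' @export
trim_primers <- function(consensus, primers, window = 150, max_edit_fraction = 0.20) {
  empty_hits <- tibble(primer_name = character(), strand = character(),
                       start = integer(), end = integer(), edits = integer(),
                       consensus_end = character())
  if (is.null(primers) || nrow(primers) == 0) {
    return(list(trimmed = consensus, hits = empty_hits))
  }
  len <- nchar(consensus)
  wlen <- min(window, len)
  best_for_end <- function(which_end) {
    text <- if (which_end == "5prime") substr(consensus, 1, wlen)
            else substr(consensus, len - wlen + 1, len)
    off <- if (which_end == "5prime") 0L else len - wlen
    best <- NULL
    for (i in seq_len(nrow(primers))) {
      plen <- nchar(primers$seq[[i]])
      if (wlen < plen) next
      allow <- ceiling(max_edit_fraction * plen)
      for (strand in c("forward", "reverse_complement")) {
        pat <- if (strand == "forward") primers$seq[[i]] else reverse_complement(primers$seq[[i]])
        f <- primer_fit(text, pat)
        if (f$edits > allow) next
        cand <- tibble(primer_name = primers$name[[i]], strand = strand,
                       start = f$start + off, end = f$end + off,
                       edits = f$edits, consensus_end = which_end)
        if (is.null(best) || cand$edits < best$edits ||
            (cand$edits == best$edits && cand$start < best$start)) {
          best <- cand
        }
      }
    }
    best
  }
  h5 <- best_for_end("5prime")
  h3 <- best_for_end("3prime")
  # the same physical primer copy must not be trimmed from both ends
  if (!is.null(h5) && !is.null(h3) && h3$start < h5$end) h3 <- NULL
  cut_from <- 1L
  cut_to <- len
  hits <- empty_hits
  if (!is.null(h5)) {
    if (len - h5$end >= 50) {
      cut_from <- h5$end + 1L
      hits <- bind_rows(hits, h5)
    } else {
      warn("trim_primers: 5' trim would leave fewer than 50 bases; skipped")
    }
  }
  if (!is.null(h3)) {
    if (h3$start - (cut_from - 1L) >= 50) {
      cut_to <- h3$start
      hits <- bind_rows(hits, h3)
    } else {
      warn("trim_primers: 3' trim would leave fewer than 50 bases; skipped")
    }
  }
  list(trimmed = substr(consensus, cut_from, cut_to), hits = hits)
}

#' Trim primers from polished consensuses, then re-merge and re-polish
#'
#' Applies [trim_primers()] to every consensus. If any hit occurred anywhere,
#' the duplicate-consensus merge and the polishing stage are re-run on the
#' trimmed set (reads are mapped against the trimmed references; read primer
#' tails fall into the unpenalized overhangs of the semi-global mapping).
#' This second pass catches redundant strand-split consensuses whose primer
#' tails kept their pre-trim identity below the merge threshold.
#'
#' @param consensuses Consensus record tibble (already polished).
#' @param reads Read tibble covering all supporting reads.
#' @param primers Primer tibble.
#' @param identity_threshold Merge identity threshold (default 0.90).
#' @param rounds,window_length,window_overlap,min_window_coverage,max_reads_per_polish,min_identity
#'   Polishing settings, as in [polish()].
#' @param window,max_edit_fraction Primer search settings.
#' @param params [align_params()].
#' @return The final consensus tibble, with attributes `"primer_hits"`
#'   (tibble over all consensuses) and `"rerun_log"` (character).
#' @export
trim_and_rerun <- function(consensuses, reads, primers,
                           identity_threshold = 0.90, rounds = 2,
                           window_length = 500, window_overlap = 50,
                           min_window_coverage = 3, max_reads_per_polish = 150,
                           min_identity = 0.60, window = 150,
                           max_edit_fraction = 0.20, params = align_params()) {
  all_hits <- list()
  trimmed <- consensuses
  for (i in seq_len(nrow(consensuses))) {
    tr <- trim_primers(consensuses$seq[[i]], primers, window, max_edit_fraction)
    trimmed$seq[[i]] <- tr$trimmed
    if (nrow(tr$hits) > 0) {
      tr$hits$consensus_id <- consensuses$consensus_id[[i]]
      all_hits[[length(all_hits) + 1]] <- tr$hits
    }
  }
  hits <- bind_rows(all_hits)
  log_lines <- character(0)
  if (nrow(hits) == 0) {
    attr(consensuses, "primer_hits") <- hits
    attr(consensuses, "rerun_log") <- log_lines
    return(consensuses)
  }
  log_lines <- c(log_lines, sprintf(
    "primer trimming: %d hit(s) across %d consensus(es); re-running duplicate merge and polishing",
    nrow(hits), length(unique(hits$consensus_id))
  ))
  merged <- merge_duplicate_consensuses(trimmed, identity_threshold, params)
  log_lines <- c(log_lines, attr(merged, "merge_log"))
  for (i in seq_len(nrow(merged))) {
    sub <- reads[reads$id %in% merged$supporting_read_ids[[i]], , drop = FALSE]
    pol <- polish(merged$seq[[i]], sub, rounds, window_length, window_overlap,
                  min_window_coverage, max_reads_per_polish, min_identity, params)
    merged$seq[[i]] <- pol$seq
    merged$polished_rounds[[i]] <- merged$polished_rounds[[i]] + pol$polished_rounds
  }
  log_lines <- c(log_lines, "post-trim re-polish complete")
  attr(merged, "primer_hits") <- hits
  attr(merged, "rerun_log") <- log_lines
  merged
}
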