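#' Map reads back to a draft consensus
#'
#' Each read is aligned semi-globally against the draft on its better strand;
#' reads whose best identity falls below `min_identity` are dropped from
#' polishing (they are typically contaminants or junk reads). CIGARs are
#' anchored to draft coordinates (0-based, half-open).
#'
#' @param reads Read tibble.
#' @param draft Non-empty draft consensus string.
#' @param params [align_params()].
#' @param min_identity Mapping identity floor (default 0.60).
#' @return A tibble with `read_id`, `orientation`, `identity`, `cigar`,
#'   `ref_start`, `ref_end`, `query_start`, `query_end` and `seq_used` (the
#'   read on the strand that was aligned). A `"dropped"` attribute lists the
#'   read ids that failed the identity floor.
#' @export
map_reads_to_draft <- function(reads, draft, params = align_params(),
                               min_identity = 0.60) {
  if (!nzchar(draft)) abort("map_reads_to_draft: empty draft")
  rows <- map(seq_len(nrow(reads)), function(i) {
    r <- best_orientation_identity(draft, reads$seq[[i]], params)
    r$read_id <- reads$id[[i]]
    r$seq_used <- if (r$orientation == "reverse_complement") {
      reverse_complement(reads$seq[[i]])
    } else {
      reads$seq[[i]]
    }
    r
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble(read_id = character(), orientation = character(),
                  identity = numeric(), cigar = character(),
                  ref_start = integer(), ref_end = integer(),
                  query_start = integer(), query_end = integer(),
                  seq_used = character())
    attr(res, "dropped") <- character(0)
    return(res)
  }
  keep <- res$identity >= min_identity
  dropped <- res$read_id[!keep]
  res <- res[keep, c("read_id", "orientation", "identity", "cigar",
                     "ref_start", "ref_end", "query_start", "query_end", "seq_used")]
  attr(res, "dropped") <- dropped
  res
}

parse_cigar <- function(cigar) {
  if (!nzchar(cigar)) return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

# Project one mapped read onto a draft window [ws, we) (0-based half-open).
# Returns the read subsegment spanning the window and the fraction of the
# window's draft positions the mapping covers, or NULL when nothing aligns.
project_read_segment <- function(mapped_row, ws, we) {
  ops <- parse_cigar(mapped_row$cigar)
  rpos <- mapped_row$ref_start
  qpos <- mapped_row$query_start
  qs <- NA_integer_
  qe <- NA_integer_
  cov <- 0L
  for (k in seq_len(nrow(ops))) {
    len <- ops$len[k]
    op <- ops$op[k]
    if (op == "M") {
      os <- max(rpos, ws); oe <- min(rpos + len, we)
      if (oe > os) {
        if (is.na(qs)) qs <- qpos + (os - rpos)
        qe <- qpos + (oe - rpos)
        cov <- cov + (oe - os)
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      os <- max(rpos, ws); oe <- min(rpos + len, we)
      if (oe > os && !is.na(qs)) cov <- cov + (oe - os)
      rpos <- rpos + len
    } else { # I: read bases between draft positions
      if (!is.na(qs) && rpos > ws && rpos < we) qe <- qpos + len
      qpos <- qpos + len
    }
    if (rpos >= we) break
  }
  if (is.na(qs) || is.na(qe) || qe <= qs) return(NULL)
  list(
    segment = substr(mapped_row$seq_used, qs + 1, qe),
    coverage = cov / (we - ws)
  )
}

polish_windows <- function(len, window_length, window_overlap) {
  if (len <= window_length) return(list(c(0L, len)))
  step <- window_length - window_overlap
  out <- list()
  s <- 0L
  repeat {
    e <- min(s + window_length, len)
    out[[length(out) + 1]] <- c(as.integer(s), as.integer(e))
    if (e >= len) break
    s <- s + step
  }
  out
}

#' One round of Racon-style polishing by backbone-anchored voting
#'
#' Reads are mapped to the draft and their alignments cast votes anchored to
#' draft coordinates: per column a substitution or deletion vote, and per
#' junction an insertion vote with the inserted string. A strict majority of
#' the covering reads changes a column (the draft itself casts one vote and
#' wins ties), and an insertion is applied when more than half of the reads
#' spanning the junction support one, taking the most frequent inserted
#' string. The draft is tiled into windows of `window_length` stepping by
#' `window_length - window_overlap`; windows spanned by fewer than
#' `min_window_coverage` read segments keep the draft segment verbatim.
#' Because every edit is anchored to draft coordinates, window outputs
#' splice exactly.
#'
#' @param draft Draft consensus string.
#' @param reads Read tibble (the cluster's reads).
#' @param window_length,window_overlap Window tiling (defaults 500 / 50).
#' @param min_window_coverage Minimum read segments to re-call a window
#'   (default 3).
#' @param min_identity Mapping identity floor (default 0.60).
#' @param min_segment_coverage Minimum fraction of a window a read segment
#'   must span to count toward the window's coverage (default 0.8).
#' @param params [align_params()].
#' @return The polished sequence. If no read maps, the draft is returned
#'   unchanged with a warning.
#' @export
polish_once <- function(draft, reads, window_length = 500, window_overlap = 50,
                        min_window_coverage = 3, min_identity = 0.60,
                        min_segment_coverage = 0.8, params = align_params()) {
  stopifnot(window_overlap < window_length)
  mapped <- map_reads_to_draft(reads, draft, params, min_identity)
  if (nrow(mapped) == 0) {
    warn("polish_once: no reads mapped to the draft; returning it unchanged")
    return(draft)
  }
  len <- nchar(draft)

  # per-column votes: codes 1..4 = A,C,G,T; 5 = deletion
  bases <- c("A", "C", "G", "T")
  pos_acc <- vector("list", nrow(mapped))
  code_acc <- vector("list", nrow(mapped))
  ins_pos <- integer(0)
  ins_str <- character(0)
  for (i in seq_len(nrow(mapped))) {
    ops <- parse_cigar(mapped$cigar[i])
    rpos <- mapped$ref_start[i]
    qpos <- mapped$query_start[i]
    pv <- integer(0); cv <- integer(0)
    for (k in seq_len(nrow(ops))) {
      l <- ops$len[k]; op <- ops$op[k]
      if (op == "M") {
        chars <- strsplit(substr(mapped$seq_used[i], qpos + 1, qpos + l), "")[[1]]
        code <- match(chars, bases)
        code[is.na(code)] <- 5L   # N and friends vote as deletion-neutral noise
        pv <- c(pv, rpos:(rpos + l - 1)); cv <- c(cv, code)
        rpos <- rpos + l; qpos <- qpos + l
      } else if (op == "D") {
        pv <- c(pv, rpos:(rpos + l - 1)); cv <- c(cv, rep(5L, l))
        rpos <- rpos + l
      } else {
        if (rpos > 0 && rpos < len) {
          ins_pos <- c(ins_pos, rpos)
          ins_str <- c(ins_str, substr(mapped$seq_used[i], qpos + 1, qpos + l))
        }
        qpos <- qpos + l
      }
    }
    pos_acc[[i]] <- pv; code_acc[[i]] <- cv
  }
  pos_all <- unlist(pos_acc); code_all <- unlist(code_acc)
  votes <- matrix(tabulate(pos_all * 5L + code_all, nbins = 5L * len), nrow = 5)
  cov <- colSums(votes)

  # window mask: columns inside at least one sufficiently covered window may
  # be re-called
  votable <- rep(FALSE, len)
  for (wn in polish_windows(len, window_length, window_overlap)) {
    ws <- wn[1]; we <- wn[2]
    nseg <- 0L
    for (i in seq_len(nrow(mapped))) {
      pr <- project_read_segment(mapped[i, ], ws, we)
      if (!is.null(pr) && pr$coverage >= min_segment_coverage) nseg <- nseg + 1L
    }
    if (nseg >= min_window_coverage) votable[(ws + 1):we] <- TRUE
  }

  draft_chars <- strsplit(draft, "")[[1]]
  draft_code <- match(draft_chars, bases)
  out_cols <- draft_chars

  recall <- votable & cov >= min_window_coverage
  for (p in which(recall)) {
    v <- votes[, p]
    dc <- draft_code[p]
    if (!is.na(dc)) v[dc] <- v[dc] + 1L   # the draft's own vote; wins ties
    top <- which.max(v)
    if (!is.na(dc) && v[top] == v[dc]) top <- dc
    out_cols[p] <- if (top == 5L) "" else bases[top]
  }

  # insertion junctions: before column p (0-based), applied on read majority
  ins_out <- character(len + 1)
  if (length(ins_pos) > 0) {
    for (p in unique(ins_pos)) {
      if (!(votable[p] && votable[p + 1])) next
      covj <- min(cov[p], cov[p + 1])
      strs <- ins_str[ins_pos == p]
      if (2L * length(strs) > covj + 1L) {   # draft votes against insertion
        tb <- sort(table(strs), decreasing = TRUE)
        ins_out[p + 1] <- names(tb)[1]
      }
    }
  }

  paste0(paste0(ins_out[seq_len(len)], out_cols, collapse = ""), ins_out[len + 1])
}

#' Iterative consensus polishing
#'
#' Applies [polish_once()] up to `rounds` times, re-mapping the reads against
#' the current sequence each round, and stops early when a round leaves the
#' sequence unchanged. When more reads are available than
#' `max_reads_per_polish`, the highest-quality reads (lowest mean error rate)
#' are used.
#'
#' @param draft Draft consensus string.
#' @param reads Read tibble.
#' @param rounds Number of polishing rounds (default 2).
#' @param max_reads_per_polish Read cap per consensus (default 150).
#' @inheritParams polish_once
#' @return A list with `seq` (the polished sequence) and `polished_rounds`
#'   (rounds actually executed).
#' @export
polish <- function(draft, reads, rounds = 2, window_length = 500,
                   window_overlap = 50, min_window_coverage = 3,
                   max_reads_per_polish = 150, min_identity = 0.60,
                   params = align_params()) {
  stopifnot(rounds >= 0)
  if (nrow(reads) > max_reads_per_polish) {
    err <- map_dbl(reads$qual, mean_error_rate)
    reads <- reads[order(err, reads$id)[seq_len(max_reads_per_polish)], ]
  }
  cur <- draft
  applied <- 0L
  for (r in seq_len(rounds)) {
    nxt <- polish_once(cur, reads, window_length, window_overlap,
                       min_window_coverage, min_identity, params = params)
    applied <- applied + 1L
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  list(seq = cur, polished_rounds = applied)
}
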