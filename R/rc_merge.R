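#' Build a consensus record tibble
#'
#' One row per consensus, carrying provenance: the contributing cluster ids,
#' the supporting read ids (the union of the member reads of those clusters),
#' and the number of polishing rounds applied so far.
#'
#' @param consensus_id Character ids.
#' @param seq Consensus sequences.
#' @param cluster_ids List of integer vectors.
#' @param supporting_read_ids List of character vectors.
#' @param polished_rounds Integer vector (default 0).
#' @return A tibble with one row per consensus and an empty
#'   `flipped_read_ids` list-column (reads whose source consensus was merged
#'   away in the opposite orientation).
#' @export
consensus_records <- function(consensus_id, seq, cluster_ids, supporting_read_ids,
                              polished_rounds = 0L) {
  tibble(
    consensus_id = consensus_id,
    seq = seq,
    cluster_ids = cluster_ids,
    supporting_read_ids = supporting_read_ids,
    polished_rounds = as.integer(polished_rounds),
    flipped_read_ids = rep(list(character(0)), length(consensus_id))
  )
}

#' Merge duplicate consensus sequences (same or opposite strand)
#'
#' All-vs-all best-strand semi-global alignment; any pair at identity of at
#' least `identity_threshold` is linked, and each connected component
#' collapses into a single record. The surviving sequence is the component
#' member with the most supporting reads (ties: longest sequence, then
#' lexicographically smallest id), kept in its own orientation; supporting
#' reads are the union over the component, and reads from members whose
#' consensus matched the survivor in reverse-complement orientation are
#' flagged in `flipped_read_ids` for strand normalization before re-polishing.
#' Transitive (component) merging makes the operation order-independent and
#' idempotent.
#'
#' @param consensuses Consensus record tibble (possibly empty).
#' @param identity_threshold Minimum identity to merge (default 0.90).
#' @param params [align_params()].
#' @return The merged consensus tibble; a `"merge_log"` attribute records the
#'   merge events.
#' @export
merge_duplicate_consensuses <- function(consensuses, identity_threshold = 0.90,
                                        params = align_params()) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  n <- nrow(consensuses)
  log_lines <- character(0)
  if (n <= 1) {
    attr(consensuses, "merge_log") <- log_lines
    return(consensuses)
  }

  edges <- matrix(integer(0), ncol = 2)
  ident <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- best_orientation_identity(consensuses$seq[[i]], consensuses$seq[[j]], params)
      ident[i, j] <- r$identity
      if (r$identity >= identity_threshold) edges <- rbind(edges, c(i, j))
    }
  }

  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_len(n)), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(seq_len(n))]

  out <- list()
  for (cm in unique(comp)) {
    idx <- which(comp == cm)
    if (length(idx) == 1) {
      out[[length(out) + 1]] <- consensuses[idx, , drop = FALSE]
      next
    }
    support <- lengths(consensuses$supporting_read_ids[idx])
    ord <- order(-support, -nchar(consensuses$seq[idx]), consensuses$consensus_id[idx])
    keep <- idx[ord[1]]
    others <- setdiff(idx, keep)
    rec <- consensuses[keep, , drop = FALSE]
    flipped <- rec$flipped_read_ids[[1]]
    for (o in others) {
      orient <- best_orientation_identity(rec$seq[[1]], consensuses$seq[[o]], params)$orientation
      if (orient == "reverse_complement") {
        flipped <- c(flipped, consensuses$supporting_read_ids[[o]])
      }
      flipped <- c(flipped, consensuses$flipped_read_ids[[o]])
    }
    rec$cluster_ids[[1]] <- sort(unique(unlist(consensuses$cluster_ids[idx])))
    rec$supporting_read_ids[[1]] <- unique(unlist(consensuses$supporting_read_ids[idx]))
    rec$flipped_read_ids[[1]] <- unique(flipped)
    ids <- consensuses$consensus_id[idx]
    pairs <- ident[idx, idx, drop = FALSE]
    log_lines <- c(log_lines, sprintf(
      "merge: component {%s} -> survivor %s (identities: %s)",
      paste(ids, collapse = ","), rec$consensus_id[[1]],
      paste(sprintf("%.3f", pairs[upper.tri(pairs)][!is.na(pairs[upper.tri(pairs)])]), collapse = ",")
    ))
    out[[length(out) + 1]] <- rec
  }
  res <- bind_rows(out)
  attr(res, "merge_log") <- log_lines
  res
}
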