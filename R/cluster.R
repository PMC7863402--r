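#' Minimizer sketch of a DNA sequence
#'
#' For every window of `w` consecutive k-mer start positions, the
#' lexicographically smallest k-mer (leftmost on ties) is selected; maximal
#' runs of an identical winning k-mer collapse to their first occurrence.
#' Positions are 0-based.
#'
#' @param seq A DNA string.
#' @param k K-mer size.
#' @param w Window size (number of consecutive k-mers per window).
#' @return A tibble with columns `kmer` and `pos`; empty when
#'   `nchar(seq) < k`.
#' @export
minimizers <- function(seq, k = 9, w = 10) {
  stopifnot(k >= 1, k <= 28, w >= 1)
  as_tibble(.minimizers_cpp(seq, as.integer(k), as.integer(w)))
}

#' Order reads for greedy clustering
#'
#' Sorts by descending expected number of correct bases (the sum over bases of
#' `1 - 10^(-q/10)`), so that the highest-confidence reads found clusters and
#' become representatives. Ties break by descending length, then by id.
#'
#' @param reads Read tibble.
#' @return The reordered tibble with an `exp_correct` column added.
#' @export
sort_reads_for_clustering <- function(reads) {
  reads$exp_correct <- map_dbl(reads$qual, function(q) sum(1 - 10^(-as.numeric(q) / 10)))
  reads[order(-reads$exp_correct, -nchar(reads$seq), reads$id), , drop = FALSE]
}

#' Greedy quality-ordered minimizer clustering of reads
#'
#' A single pass over the reads in [sort_reads_for_clustering()] order. Each
#' read is compared against existing cluster representatives by the fraction
#' of its minimizers found among the representative's k-mers; it joins the
#' cluster maximizing that shared fraction if the maximum reaches
#' `shared_fraction_threshold`, and otherwise founds a new cluster with itself
#' as representative. Reads are used on the strand given: reverse-complement
#' reads of the same amplicon are expected to form separate clusters, which
#' the downstream duplicate-merge stage reunites. Representative sketches are
#' frozen at cluster founding.
#'
#' @param reads Read tibble (non-empty).
#' @param k,w Minimizer parameters (defaults 9 and 10; calibrated for reads
#'   with roughly 5-12 percent errors).
#' @param shared_fraction_threshold Minimum shared minimizer fraction to join
#'   an existing cluster (default 0.12).
#' @return A tibble of clusters: `cluster_id`, `representative_id`, `size`,
#'   `member_ids` (list), `minimizer_set` (list of the representative's
#'   minimizer k-mers).
#' @export
cluster_reads <- function(reads, k = 9, w = 10, shared_fraction_threshold = 0.12) {
  if (nrow(reads) == 0) abort("cluster_reads: no reads to cluster")
  stopifnot(shared_fraction_threshold > 0, shared_fraction_threshold <= 1)
  sorted <- sort_reads_for_clustering(reads)

  rep_ids <- character(0)
  rep_kmers <- list()       # full k-mer index of each representative
  rep_minis <- list()       # representative minimizer sketch (reported)
  members <- list()

  for (i in seq_len(nrow(sorted))) {
    s <- sorted$seq[[i]]
    mins <- .minimizers_cpp(s, as.integer(k), as.integer(w))$kmer
    best <- 0
    best_c <- 0L
    if (length(rep_ids) > 0 && length(mins) > 0) {
      for (ci in seq_along(rep_ids)) {
        fr <- mean(mins %in% rep_kmers[[ci]])
        if (fr > best) {
          best <- fr
          best_c <- ci
        }
      }
    }
    if (best_c > 0L && best >= shared_fraction_threshold) {
      members[[best_c]] <- c(members[[best_c]], sorted$id[[i]])
    } else {
      ci <- length(rep_ids) + 1L
      rep_ids[ci] <- sorted$id[[i]]
      rep_kmers[[ci]] <- all_kmers(s, k)
      rep_minis[[ci]] <- unique(mins)
      members[[ci]] <- sorted$id[[i]]
    }
  }

  tibble(
    cluster_id = seq_along(rep_ids),
    representative_id = rep_ids,
    size = lengths(members),
    member_ids = members,
    minimizer_set = rep_minis
  )
}

all_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Write cluster assignments as TSV
#'
#' Columns: `cluster_id`, `read_id`, `is_representative` (0/1).
#'
#' @param clusters Cluster tibble from [cluster_reads()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cluster_assignments <- function(clusters, path) {
  rows <- purrr::map2(clusters$cluster_id, seq_len(nrow(clusters)), function(cid, i) {
    ids <- clusters$member_ids[[i]]
    tibble(
      cluster_id = cid, read_id = ids,
      is_representative = as.integer(ids == clusters$representative_id[[i]])
    )
  })
  tab <- bind_rows(rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
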