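#' Alignment scoring parameters
#'
#' Affine-gap scores shared by the partial-order aligner, the pairwise
#' aligner, the duplicate-consensus merge and the polisher. A single gap of
#' length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param match Match score (> 0; default 2).
#' @param mismatch Mismatch score (<= 0; default -2).
#' @param gap_open Cost of the first base of a gap (<= 0; default -4).
#' @param gap_extend Cost of each further gap base (<= 0; default -2).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -2, gap_open = -4, gap_extend = -2) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)),
    class = "align_params"
  )
}

#' Create an empty partial-order alignment graph
#'
#' The graph is a weighted DAG over single bases with virtual start/end
#' markers; `start_w`/`end_w` count sequences beginning/ending at each node,
#' `support` counts sequences visiting a node, and edge weights count
#' traversals. `topo` holds a valid topological order (0-based node ids).
#'
#' @return A list of class `poa_graph`.
#' @export
poa_graph <- function() {
  structure(.poa_empty_cpp(), class = "poa_graph")
}

#' Number of nodes in a POA graph
#' @param graph A `poa_graph`.
#' @return Integer node count.
#' @export
poa_size <- function(graph) nchar(graph$bases)

#' Align a sequence to a POA graph
#'
#' Global affine-gap dynamic programming over all start-to-end paths of the
#' DAG, processed in topological order. Ties prefer match over mismatch over
#' deletion (graph node skipped) over insertion (sequence base unaligned),
#' and among equal predecessors the lowest topological index. Aligning to an
#' empty graph yields the trivial all-insertion path.
#'
#' @param graph A `poa_graph`.
#' @param seq Non-empty DNA string.
#' @param params [align_params()].
#' @return A list with `score` and `path`, a tibble of alignment columns with
#'   0-based `node` (NA for insertions) and `qpos` (NA for deletions).
#' @export
align_to_graph <- function(graph, seq, params = align_params()) {
  if (!nzchar(seq)) abort("align_to_graph: empty sequence")
  a <- .poa_align_cpp(graph, seq, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  path <- tibble(
    node = ifelse(a$col_node < 0, NA_integer_, a$col_node),
    qpos = ifelse(a$col_qpos < 0, NA_integer_, a$col_qpos)
  )
  list(score = a$score, path = path)
}

#' Add an aligned sequence to a POA graph
#'
#' Matched columns increment node support; mismatches and insertions reuse an
#' existing same-base branch when that is acyclic-safe and otherwise create
#' nodes; edge weights are incremented along the traversed path.
#'
#' @param graph A `poa_graph`.
#' @param seq The aligned sequence.
#' @param alignment Result of [align_to_graph()] (or its `path` tibble).
#' @return The updated `poa_graph`.
#' @export
add_to_graph <- function(graph, seq, alignment) {
  path <- if (is.data.frame(alignment)) alignment else alignment$path
  cn <- ifelse(is.na(path$node), -1L, as.integer(path$node))
  cq <- ifelse(is.na(path$qpos), -1L, as.integer(path$qpos))
  structure(.poa_add_cpp(graph, seq, cn, cq), class = "poa_graph")
}

#' Heaviest-path consensus of a POA graph
#'
#' Dynamic programming over the topological order maximizing total edge
#' weight from start to end; ties break toward higher node support, then
#' lower topological index.
#'
#' @param graph A non-empty `poa_graph`.
#' @return The consensus DNA string.
#' @export
consensus_from_graph <- function(graph) {
  .poa_consensus_graph_cpp(graph)
}

#' One-shot POA consensus of a set of sequences
#'
#' Sequences are aligned and added incrementally in the given order (for
#' cluster drafts: member order, representative first) and the heaviest path
#' is returned. POA is order-sensitive; the canonical order is part of the
#' contract.
#'
#' @param seqs Non-empty character vector of DNA strings.
#' @param params [align_params()].
#' @return The consensus DNA string.
#' @examples
#' poa_consensus(c("ACGT", "ACGT", "ACTT"))  # "ACGT"
#' @export
poa_consensus <- function(seqs, params = align_params()) {
  if (length(seqs) == 0) abort("poa_consensus: empty sequence list")
  .poa_consensus_cpp(seqs, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
}
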