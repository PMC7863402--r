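#' Tidy the consensus table of a pipeline run
#'
#' One row per final consensus: id, length, supporting-read count, source
#' clusters and polishing rounds.
#'
#' @param x A `barcode_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.barcode_run <- function(x, ...) {
  tibble(
    consensus_id = x$consensus$consensus_id,
    length = nchar(x$consensus$seq),
    supporting_reads = lengths(x$consensus$supporting_read_ids),
    n_clusters = lengths(x$consensus$cluster_ids),
    polished_rounds = x$consensus$polished_rounds
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `barcode_run`.
#' @param ... Unused.
#' @return A one-row tibble: reads in/used, cluster counts, consensus count
#'   and primer hit count.
#' @exportS3Method generics::glance
glance.barcode_run <- function(x, ...) {
  tibble(
    n_reads_in = x$n_reads_in,
    n_reads_used = x$n_reads_used,
    n_clusters = nrow(x$clusters),
    n_clusters_passing = nrow(x$clusters_passing),
    n_consensus = nrow(x$consensus),
    n_primer_hits = if (is.null(x$primer_hits)) 0L else nrow(x$primer_hits)
  )
}

#' Plot cluster sizes and the abundance threshold of a run
#'
#' Bar chart of cluster sizes, with the abundance cutoff drawn as a dashed
#' line; clusters that yielded a consensus are highlighted.
#'
#' @param object A `barcode_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.barcode_run <- function(object, ...) {
  df <- tibble(
    cluster_id = factor(object$clusters$cluster_id),
    size = object$clusters$size,
    passing = object$clusters$cluster_id %in% object$clusters_passing$cluster_id
  )
  cutoff <- object$config$abundance_ratio * object$n_reads_used
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_id, y = .data$size,
                                   fill = .data$passing)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
                               name = "yields consensus") +
    ggplot2::labs(x = "cluster", y = "reads",
                  title = "Cluster sizes and abundance threshold") +
    ggplot2::theme_minimal()
}
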