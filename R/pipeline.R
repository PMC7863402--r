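#' Pipeline configuration
#'
#' All tunable parameters of the consensus pipeline in one validated object.
#' Defaults follow the tool's standard settings: no subsampling, a 10%
#' cluster abundance threshold, a 90% duplicate-merge identity and 2 rounds
#' of windowed polishing.
#'
#' @param max_error_rate Quality filter: maximum mean per-base error
#'   probability (default 0.10).
#' @param target_length,length_window Optional read-length filter.
#' @param sample_size Reads to subsample after filtering; 0 = off (default).
#' @param seed Seed driving subsampling (default 1234).
#' @param k,w,shared_fraction_threshold Clustering parameters (defaults 9,
#'   10, 0.12; see [cluster_reads()]).
#' @param abundance_ratio A cluster yields a consensus only when its size is
#'   strictly greater than `abundance_ratio` times the reads that entered
#'   clustering (default 0.10).
#' @param rc_identity_threshold Duplicate-consensus merge identity
#'   (default 0.90).
#' @param rounds Polishing rounds (default 2).
#' @param window_length,window_overlap,min_window_coverage Polishing windows
#'   (defaults 500 / 50 / 3).
#' @param max_reads_per_consensus Read cap for the POA draft (default 150,
#'   highest-quality first).
#' @param max_reads_per_polish Read cap per polishing round (default 150).
#' @param min_mapping_identity Identity floor for read-to-draft mapping
#'   (default 0.60).
#' @param primer_window,max_edit_fraction Primer search window (150) and edit
#'   tolerance as a fraction of primer length (0.20).
#' @param match,mismatch,gap_open,gap_extend Alignment scores; see
#'   [align_params()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_error_rate = 0.10, target_length = NULL,
                            length_window = NULL, sample_size = 0, seed = 1234,
                            k = 9, w = 10, shared_fraction_threshold = 0.12,
                            abundance_ratio = 0.10, rc_identity_threshold = 0.90,
                            rounds = 2, window_length = 500, window_overlap = 50,
                            min_window_coverage = 3, max_reads_per_consensus = 150,
                            max_reads_per_polish = 150, min_mapping_identity = 0.60,
                            primer_window = 150, max_edit_fraction = 0.20,
                            match = 2, mismatch = -2, gap_open = -4, gap_extend = -2) {
  stopifnot(abundance_ratio > 0, abundance_ratio <= 1, sample_size >= 0, rounds >= 0)
  cfg <- list(
    max_error_rate = max_error_rate, target_length = target_length,
    length_window = length_window, sample_size = sample_size, seed = seed,
    k = k, w = w, shared_fraction_threshold = shared_fraction_threshold,
    abundance_ratio = abundance_ratio, rc_identity_threshold = rc_identity_threshold,
    rounds = rounds, window_length = window_length, window_overlap = window_overlap,
    min_window_coverage = min_window_coverage,
    max_reads_per_consensus = max_reads_per_consensus,
    max_reads_per_polish = max_reads_per_polish,
    min_mapping_identity = min_mapping_identity,
    primer_window = primer_window, max_edit_fraction = max_edit_fraction,
    params = align_params(match, mismatch, gap_open, gap_extend)
  )
  structure(cfg, class = "pipeline_config")
}

#' Keep clusters above the abundance threshold
#'
#' A cluster passes only when it holds strictly more reads than
#' `ratio * total_reads` ("more reads than" the threshold, so a cluster
#' sitting exactly on the boundary is dropped). Output is ordered by
#' descending size.
#'
#' @param clusters Cluster tibble from [cluster_reads()].
#' @param total_reads Number of reads that entered clustering.
#' @param ratio Abundance ratio (default 0.10).
#' @return The filtered, size-ordered cluster tibble.
#' @examples
#' # sizes 150/100/40/10 of 300 at ratio 0.10 (threshold 30): 10 is dropped
#' @export
abundance_filter <- function(clusters, total_reads, ratio = 0.10) {
  keep <- clusters$size > ratio * total_reads
  out <- clusters[keep, , drop = FALSE]
  out[order(-out$size, out$cluster_id), , drop = FALSE]
}

#' Run the full barcode consensus pipeline
#'
#' Filter -> subsample -> cluster -> abundance filter -> per-cluster POA
#' draft -> duplicate-consensus merge -> polish -> (when primers are given)
#' primer trimming with a re-merge/re-polish pass. The run is fully
#' determined by the input bytes, the configuration and the seed.
#'
#' @param fastq Path to the input FASTQ, or a read tibble from
#'   [read_fastq()].
#' @param config A [pipeline_config()].
#' @param primers Optional primer tibble ([read_primers()]) or path to a
#'   primer FASTA.
#' @param outdir Optional output directory; when given, writes
#'   `consensus.fasta`, `cluster_assignments.tsv`, `primer_hits.tsv` (if
#'   primers were supplied), `consensus_<i>/reads.fastq`, `run.log` and
#'   `config.yaml`.
#' @return An object of class `barcode_run`: a list with `consensus` (the
#'   final consensus record tibble), `clusters`, `clusters_passing`,
#'   `n_reads_in`, `n_reads_used`, `primer_hits`, `log` and `config`.
#'   Errors with class `barcodeid_no_consensus` when no reads survive
#'   filtering or no cluster passes the abundance threshold.
#' @export
run_pipeline <- function(fastq, config = pipeline_config(), primers = NULL,
                         outdir = NULL) {
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  n_in <- nrow(reads)
  note("input: %d reads", n_in)
  if (is.character(primers)) primers <- read_primers(primers)

  reads <- filter_reads(reads, config$max_error_rate, config$target_length,
                        config$length_window)
  fs <- attr(reads, "filter_summary")
  note("filter: kept %d, dropped %d", fs$kept, fs$dropped)
  if (nrow(reads) == 0) {
    abort("no consensus formed: no reads passed filtering",
          class = "barcodeid_no_consensus")
  }
  reads <- subsample_reads(reads, config$sample_size, config$seed)
  n_used <- nrow(reads)
  note("clustering %d reads (k=%d, w=%d, threshold=%.2f)", n_used,
       config$k, config$w, config$shared_fraction_threshold)

  clusters <- cluster_reads(reads, config$k, config$w, config$shared_fraction_threshold)
  note("clustering produced %d clusters (largest %d)", nrow(clusters), max(clusters$size))
  passing <- abundance_filter(clusters, n_used, config$abundance_ratio)
  note("abundance filter (> %.2f x %d = %.1f reads): %d cluster(s) pass",
       config$abundance_ratio, n_used, config$abundance_ratio * n_used, nrow(passing))
  if (nrow(passing) == 0) {
    abort("no consensus formed: no cluster passed the abundance threshold",
          class = "barcodeid_no_consensus")
  }

  read_by_id <- setNames(seq_len(nrow(reads)), reads$id)
  drafts <- map_chr(seq_len(nrow(passing)), function(i) {
    ids <- passing$member_ids[[i]]
    ids <- head(ids, config$max_reads_per_consensus)  # member order = quality order
    poa_consensus(reads$seq[read_by_id[ids]], config$params)
  })
  note("drafts: %s", paste(sprintf("cluster %d (%d reads, %d bp)",
                                   passing$cluster_id, passing$size,
                                   nchar(drafts)), collapse = "; "))

  cons <- consensus_records(
    consensus_id = sprintf("cluster_%d", passing$cluster_id),
    seq = drafts,
    cluster_ids = as.list(passing$cluster_id),
    supporting_read_ids = passing$member_ids
  )
  cons <- merge_duplicate_consensuses(cons, config$rc_identity_threshold, config$params)
  log_lines <- c(log_lines, attr(cons, "merge_log"))
  note("after duplicate merge: %d consensus(es)", nrow(cons))

  for (i in seq_len(nrow(cons))) {
    sub <- reads[reads$id %in% cons$supporting_read_ids[[i]], , drop = FALSE]
    pol <- polish(cons$seq[[i]], sub, config$rounds, config$window_length,
                  config$window_overlap, config$min_window_coverage,
                  config$max_reads_per_polish, config$min_mapping_identity,
                  config$params)
    cons$seq[[i]] <- pol$seq
    cons$polished_rounds[[i]] <- pol$polished_rounds
    note("polished %s: %d round(s), %d bp", cons$consensus_id[[i]],
         pol$polished_rounds, nchar(pol$seq))
  }

  primer_hits <- NULL
  if (!is.null(primers) && nrow(primers) > 0) {
    cons <- trim_and_rerun(cons, reads, primers,
                           identity_threshold = config$rc_identity_threshold,
                           rounds = config$rounds,
                           window_length = config$window_length,
                           window_overlap = config$window_overlap,
                           min_window_coverage = config$min_window_coverage,
                           max_reads_per_polish = config$max_reads_per_polish,
                           min_identity = config$min_mapping_identity,
                           window = config$primer_window,
                           max_edit_fraction = config$max_edit_fraction,
                           params = config$params)
    primer_hits <- attr(cons, "primer_hits")
    log_lines <- c(log_lines, attr(cons, "rerun_log"))
    note("primer stage: %d hit(s); %d final consensus(es)",
         if (is.null(primer_hits)) 0L else nrow(primer_hits), nrow(cons))
  }

  # final naming: consensus_<rank>_<supporting reads>, by descending support
  support <- lengths(cons$supporting_read_ids)
  cons <- cons[order(-support, cons$consensus_id), , drop = FALSE]
  cons$consensus_id <- sprintf("consensus_%d_%d", seq_len(nrow(cons)),
                               lengths(cons$supporting_read_ids))
  note("final output: %d consensus(es)", nrow(cons))

  run <- structure(list(
    consensus = cons, clusters = clusters, clusters_passing = passing,
    n_reads_in = n_in, n_reads_used = n_used,
    primer_hits = primer_hits, log = log_lines, config = config
  ), class = "barcode_run")

  if (!is.null(outdir)) write_run_outputs(run, reads, outdir)
  run
}

write_run_outputs <- function(run, reads, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(tibble(id = run$consensus$consensus_id, seq = unlist(run$consensus$seq)),
              file.path(outdir, "consensus.fasta"))
  write_cluster_assignments(run$clusters, file.path(outdir, "cluster_assignments.tsv"))
  if (!is.null(run$primer_hits)) {
    write.table(run$primer_hits, file.path(outdir, "primer_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (i in seq_len(nrow(run$consensus))) {
    d <- file.path(outdir, sprintf("consensus_%d", i))
    dir.create(d, showWarnings = FALSE)
    sub <- reads[reads$id %in% run$consensus$supporting_read_ids[[i]], , drop = FALSE]
    write_fastq(sub, file.path(d, "reads.fastq"))
  }
  writeLines(run$log, file.path(outdir, "run.log"))
  cfg <- run$config
  cfg$params <- unclass(cfg$params)
  cfg <- lapply(unclass(cfg), function(x) if (is.null(x)) NA else x)
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' @export
print.barcode_run <- function(x, ...) {
  cat(sprintf("<barcode_run> %d reads in, %d used, %d cluster(s), %d consensus(es)\n",
              x$n_reads_in, x$n_reads_used, nrow(x$clusters), nrow(x$consensus)))
  for (i in seq_len(nrow(x$consensus))) {
    cat(sprintf("  %s: %d bp, %d supporting reads, %d polish round(s)\n",
                x$consensus$consensus_id[[i]], nchar(x$consensus$seq[[i]]),
                length(x$consensus$supporting_read_ids[[i]]),
                x$consensus$polished_rounds[[i]]))
  }
  invisible(x)
}
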