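#' Read a 4-line FASTQ file into a tibble of reads
#'
#' Reads demultiplexed long-read amplicon data. Each record becomes one row;
#' quality strings are decoded from phred+33 into integer vectors held in a
#' list-column. Sequences are normalized in a fixed order: uppercased, then
#' `U` mapped to `T`, then any remaining character outside `{A,C,G,T,N}`
#' replaced by `N`. The read id is the first whitespace-delimited token of the
#' header; the remainder is kept as `desc` but never used as a key.
#' Gzip-compressed files are detected by their magic bytes and decompressed
#' transparently. Multi-line FASTQ and phred+64 dialects are rejected.
#'
#' @param path Path to a FASTQ (optionally gzipped) file.
#' @return A tibble with columns `id`, `desc`, `seq` and `qual` (list of
#'   integer phred scores, one per base), in file order. An empty file yields
#'   a zero-row tibble.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' read_fastq(f)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  lines <- read_text_lines(path)
  empty <- tibble(
    id = character(), desc = character(), seq = character(),
    qual = list()
  )
  if (length(lines) == 0) return(empty)
  if (length(lines) %% 4 != 0) {
    abort(sprintf(
      "malformed FASTQ: truncated record %d (file has %d lines, not a multiple of 4)",
      length(lines) %/% 4 + 1, length(lines)
    ))
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seq <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0) abort(sprintf("malformed FASTQ: record %d header does not start with '@'", bad[1]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0) abort(sprintf("malformed FASTQ: record %d separator line does not start with '+'", bad[1]))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ: record %d sequence and quality lengths differ", bad[1]))
  }

  hdr <- substring(hdr, 2)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")

  seq <- normalize_seq(seq)
  phred <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  bad <- which(vapply(phred, function(p) length(p) > 0 && (min(p) < 0 || max(p) > 93), logical(1)))
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ: record %d has quality characters outside phred+33 [0, 93]", bad[1]))
  }
  tibble(id = id, desc = desc, seq = seq, qual = phred)
}

# uppercase -> U to T -> anything outside ACGTN to N (fixed order)
normalize_seq <- function(x) {
  x <- chartr("U", "T", toupper(x))
  gsub("[^ACGTN]", "N", x)
}

read_text_lines <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 2)
  close(con)
  gz <- length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  con <- if (gz) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Write sequences to a FASTA file
#'
#' Standard FASTA output with 80-column line wrapping.
#'
#' @param records A tibble/data.frame with columns `id` and `seq`, or a named
#'   character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- tibble(id = names(records), seq = unname(records))
  }
  if (nrow(records) > 0 && anyDuplicated(records$id) > 0) {
    abort("FASTA record ids must be unique")
  }
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    s <- records$seq[[i]]
    starts <- seq(1, max(1, nchar(s)), by = 80)
    writeLines(c(paste0(">", records$id[[i]]), substring(s, starts, pmin(starts + 79, nchar(s)))), con)
  }
  invisible(path)
}

#' Write reads back out as 4-line FASTQ (phred+33)
#'
#' @param reads A read tibble as returned by [read_fastq()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    hdr <- if (nzchar(reads$desc[[i]] %||% "")) paste(reads$id[[i]], reads$desc[[i]]) else reads$id[[i]]
    writeLines(c(
      paste0("@", hdr),
      reads$seq[[i]],
      "+",
      intToUtf8(reads$qual[[i]] + 33L)
    ), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of IUPAC nucleotide sequences
#'
#' Vectorized; every IUPAC ambiguity code maps to its complement (R to Y,
#' S to S, W to W, K to M, B to V, D to H, N to N). The operation is an
#' involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq Character vector of IUPAC sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AACG")  # "CGTT"
#' @export
reverse_complement <- function(seq) {
  .rc_cpp(toupper(seq))
}

#' Mean per-base error probability of a quality vector
#'
#' The arithmetic mean of `10^(-q/10)` over the phred scores of a read.
#'
#' @param qual Integer (or numeric) vector of phred scores.
#' @return A probability in `[0, 1]`.
#' @examples
#' mean_error_rate(c(20, 20, 20))  # 0.01
#' @export
mean_error_rate <- function(qual) {
  if (length(qual) == 0) abort("mean_error_rate: empty quality vector")
  mean(10^(-as.numeric(qual) / 10))
}
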