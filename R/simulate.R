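#' Random reference sequence
#'
#' Uniform i.i.d. bases, fully determined by the seed.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
random_reference <- function(length, seed = 1) {
  stopifnot(length >= 1)
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                               collapse = ""))
}

# per-base corruption: each position independently substituted, gains an
# inserted base after it, or is deleted, at rate * mix probabilities.
# expects the RNG to be managed by the caller.
corrupt_chars <- function(chars, rate, mix) {
  n <- length(chars)
  if (n == 0 || rate <= 0) return(paste(chars, collapse = ""))
  bases <- c("A", "C", "G", "T")
  p_del <- rate * mix[["del"]]
  p_sub <- rate * mix[["sub"]]
  ev <- runif(n)
  out <- chars
  idx_del <- which(ev < p_del)
  idx_sub <- which(ev >= p_del & ev < p_del + p_sub)
  idx_ins <- which(ev >= p_del + p_sub & ev < rate)
  if (length(idx_sub) > 0) {
    cur <- match(chars[idx_sub], bases)
    cur[is.na(cur)] <- 1L
    shift <- sample.int(3, length(idx_sub), replace = TRUE)
    out[idx_sub] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  if (length(idx_ins) > 0) {
    out[idx_ins] <- paste0(out[idx_ins], sample(bases, length(idx_ins), replace = TRUE))
  }
  if (length(idx_del) > 0) out[idx_del] <- ""
  paste(out, collapse = "")
}

#' Mutate a reference by planting substitutions and indels
#'
#' Events are drawn per base at the given divergence rate with the standard
#' substitution/insertion/deletion mix, so the realized alignment identity to
#' the original is close to `1 - divergence`.
#'
#' @param ref Reference DNA string.
#' @param divergence Per-base event rate in `[0, 1)`.
#' @param seed Integer seed.
#' @param mix Named event mix summing to 1 (default
#'   `c(sub = 0.4, ins = 0.3, del = 0.3)`).
#' @return The mutated DNA string.
#' @export
mutate_reference <- function(ref, divergence, seed = 1,
                             mix = c(sub = 0.4, ins = 0.3, del = 0.3)) {
  stopifnot(divergence >= 0, divergence < 1, abs(sum(mix) - 1) < 1e-9)
  if (divergence == 0) return(ref)
  withr::with_seed(seed, corrupt_chars(strsplit(ref, "")[[1]], divergence, mix))
}

expand_iupac_random <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  masks <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  paste(vapply(chars, function(c) {
    opts <- masks[[c]]
    if (is.null(opts)) abort(sprintf("'%s' is not an IUPAC code", c))
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Simulate noisy long amplicon reads
#'
#' Emulates ONT-like amplicon data: per read, a source reference is taken, a
#' per-read error rate is drawn from a truncated normal, optional primers are
#' attached (forward primer prepended, reverse-complemented reverse primer
#' appended) *before* corruption, the sequence is corrupted by i.i.d.
#' per-base substitution/insertion/deletion events, the whole read is
#' reverse-complemented with probability `strand_prob`, and a uniform phred
#' string consistent with the drawn error rate
#' (`q = round(-10 * log10(rate))`) is assigned. Setting
#' `contaminant_fraction > 0` adds off-target reads from an unrelated random
#' reference.
#'
#' @param refs Named character vector of references, or a tibble with
#'   columns `name` and `seq`.
#' @param n_per_ref Reads per reference (>= 1).
#' @param mean_error_rate,per_read_sd Error-rate distribution (defaults 0.07
#'   and 0.02, truncated to `[0.005, 0.25]`; a mean and sd of exactly 0
#'   produce error-free reads).
#' @param mix Event mix, summing to 1.
#' @param strand_prob Probability a read is reverse-complemented
#'   (default 0.5).
#' @param primers Optional `list(fwd = , rev = )` of primer sequences (IUPAC
#'   allowed; ambiguity codes are resolved randomly per read).
#' @param contaminant_fraction Fraction of additional contaminant reads
#'   relative to the on-target total (default 0).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list with `references` (tibble `name`, `seq`), `reads` (a read
#'   tibble as from [read_fastq()]) and `truth` (tibble `read_id`,
#'   `ref_name`, `strand`, `error_rate`).
#' @export
simulate_reads <- function(refs, n_per_ref, mean_error_rate = 0.07,
                           per_read_sd = 0.02,
                           mix = c(sub = 0.4, ins = 0.3, del = 0.3),
                           strand_prob = 0.5, primers = NULL,
                           contaminant_fraction = 0, seed = 1) {
  stopifnot(n_per_ref >= 1, abs(sum(mix) - 1) < 1e-9,
            strand_prob >= 0, strand_prob <= 1)
  if (is.character(refs)) {
    if (is.null(names(refs))) names(refs) <- sprintf("ref_%d", seq_along(refs))
    refs <- tibble(name = names(refs), seq = unname(refs))
  }
  error_free <- (mean_error_rate == 0 && per_read_sd == 0)

  withr::with_seed(seed, {
    src_names <- rep(refs$name, each = n_per_ref)
    src_seqs <- rep(refs$seq, each = n_per_ref)
    if (contaminant_fraction > 0) {
      n_cont <- round(contaminant_fraction * length(src_names))
      if (n_cont > 0) {
        cont <- paste(sample(c("A", "C", "G", "T"),
                             round(mean(nchar(refs$seq))), replace = TRUE),
                      collapse = "")
        src_names <- c(src_names, rep("contaminant", n_cont))
        src_seqs <- c(src_seqs, rep(cont, n_cont))
      }
    }
    n <- length(src_names)
    ids <- sprintf("read_%05d", seq_len(n))
    rates <- if (error_free) rep(0, n) else {
      pmin(pmax(rnorm(n, mean_error_rate, per_read_sd), 0.005), 0.25)
    }
    flip <- runif(n) < strand_prob

    seqs <- character(n)
    quals <- vector("list", n)
    for (i in seq_len(n)) {
      s <- src_seqs[i]
      if (!is.null(primers)) {
        s <- paste0(expand_iupac_random(primers$fwd), s,
                    reverse_complement(expand_iupac_random(primers$rev)))
      }
      s <- corrupt_chars(strsplit(s, "")[[1]], rates[i], mix)
      if (flip[i]) s <- reverse_complement(s)
      q <- if (rates[i] <= 0) 93L else max(1L, min(93L, as.integer(round(-10 * log10(rates[i])))))
      seqs[i] <- s
      quals[[i]] <- rep(q, nchar(s))
    }

    list(
      references = refs,
      reads = tibble(id = ids, desc = "", seq = seqs, qual = quals),
      truth = tibble(
        read_id = ids, ref_name = src_names,
        strand = ifelse(flip, "reverse_complement", "forward"),
        error_rate = rates
      )
    )
  })
}

#' Consensus accuracy against a known truth sequence
#'
#' The accuracy metric used throughout: the consensus is aligned to the truth
#' semi-globally on its better strand, and the identity is the sum of matched
#' columns divided by the alignment length.
#'
#' @param consensus,truth Non-empty DNA strings.
#' @param params [align_params()].
#' @return Identity in `[0, 1]`.
#' @export
evaluate_accuracy <- function(consensus, truth, params = align_params()) {
  best_orientation_identity(consensus, truth, params)$identity
}

#' Accuracy in the conventional "percent (mismatches/length)" format
#'
#' For example `"98.6% (10/726)"`; an exact match over 709 columns prints as
#' `"100% (0/709)"`.
#'
#' @param consensus,truth Non-empty DNA strings.
#' @param params [align_params()].
#' @return A formatted string.
#' @export
format_accuracy <- function(consensus, truth, params = align_params()) {
  r <- best_orientation_identity(consensus, truth, params)
  mism <- r$alignment_length - r$matches
  if (mism == 0) {
    sprintf("100%% (0/%d)", r$alignment_length)
  } else {
    sprintf("%.1f%% (%d/%d)", 100 * r$matches / r$alignment_length,
            mism, r$alignment_length)
  }
}
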