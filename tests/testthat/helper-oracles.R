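# Independent reference implementations used as oracles. These are written
# as plain, loop-based R on purpose: they share no code with the package's
# C++ kernels.

# Affine-gap (Gotoh) alignment score, global or overlap (free terminal gaps).
ref_gotoh_score <- function(a, b, match = 2, mismatch = -2,
                            gap_open = -4, gap_extend = -2,
                            mode = c("global", "overlap")) {
  mode <- match.arg(mode)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    if (mode == "overlap") M[i, 1] <- 0
    else D[i, 1] <- gap_open + (i - 2) * gap_extend
  }
  for (j in 2:(m + 1)) {
    if (mode == "overlap") M[1, j] <- 0
    else I[1, j] <- gap_open + (j - 2) * gap_extend
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], D[i - 1, j - 1], I[i - 1, j - 1]) + s
      D[i, j] <- max(M[i - 1, j] + gap_open, D[i - 1, j] + gap_extend,
                     I[i - 1, j] + gap_open)
      I[i, j] <- max(M[i, j - 1] + gap_open, D[i, j - 1] + gap_open,
                     I[i, j - 1] + gap_extend)
    }
  }
  if (mode == "global") {
    max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
  } else {
    best <- 0
    for (j in 1:(m + 1)) best <- max(best, M[n + 1, j], D[n + 1, j], I[n + 1, j])
    for (i in 1:(n + 1)) best <- max(best, M[i, m + 1], D[i, m + 1], I[i, m + 1])
    best
  }
}

# Minimum unit-cost edits of the best occurrence of `pattern` anywhere in
# `text` (free text ends, pattern fully consumed).
ref_best_occurrence_edits <- function(text, pattern) {
  P <- strsplit(pattern, "")[[1]]
  T <- strsplit(text, "")[[1]]
  m <- length(P)
  n <- length(T)
  prev <- rep(0L, n + 1)
  for (i in seq_len(m)) {
    cur <- integer(n + 1)
    cur[1] <- i
    for (j in seq_len(n)) {
      cur[j + 1] <- min(prev[j] + as.integer(P[i] != T[j]),
                        prev[j + 1] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)
}

# All window minima of consecutive k-mers, as a set of k-mer strings.
ref_minimizer_kmers <- function(seq, k, w) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  nk <- length(kmers)
  out <- character(0)
  for (s in 1:max(1, nk - w + 1)) {
    win <- kmers[s:min(s + w - 1, nk)]
    out <- c(out, min(win))
  }
  unique(out)
}

# random read tibble with uniform quality
make_reads <- function(seqs, q = 30, ids = sprintf("r%03d", seq_along(seqs))) {
  qs <- rep_len(as.integer(q), length(seqs))
  tibble::tibble(
    id = ids, desc = "",
    seq = seqs,
    qual = Map(function(l, qq) rep(qq, l), nchar(seqs), qs)
  )
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Enumerate every start-to-end path of a poa_graph and score it under the
# package's stated majority objective: sum over traversed edges (virtual
# start/end included) of 2*w - (n_seq + 1).
ref_poa_paths <- function(g) {
  n_seq <- sum(g$start_w)
  pen <- n_seq + 1
  N <- nchar(g$bases)
  bases <- strsplit(g$bases, "")[[1]]
  adj <- vector("list", N)
  for (k in seq_along(g$edge_from)) {
    adj[[g$edge_from[k] + 1]] <- rbind(adj[[g$edge_from[k] + 1]],
                                       c(g$edge_to[k] + 1, g$edge_weight[k]))
  }
  paths <- list()
  walk <- function(v, acc_str, acc_score) {
    if (g$end_w[v] > 0) {
      paths[[length(paths) + 1]] <<- list(
        str = acc_str, score = acc_score + 2 * g$end_w[v] - pen)
    }
    for (r in seq_len(NROW(adj[[v]]))) {
      u <- adj[[v]][r, 1]
      w <- adj[[v]][r, 2]
      walk(u, paste0(acc_str, bases[u]), acc_score + 2 * w - pen)
    }
  }
  for (v in which(g$start_w > 0)) {
    walk(v, bases[v], 2 * g$start_w[v] - pen)
  }
  paths
}
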