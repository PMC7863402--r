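build_graph <- function(seqs) {
  g <- poa_graph()
  for (s in seqs) g <- add_to_graph(g, s, align_to_graph(g, s))
  g
}

check_graph_invariants <- function(g) {
  n <- poa_size(g)
  out_w <- rep(0L, n)
  for (k in seq_along(g$edge_from)) {
    out_w[g$edge_from[k] + 1] <- out_w[g$edge_from[k] + 1] + g$edge_weight[k]
  }
  # every sequence leaving a node does so over exactly one edge (or ends)
  expect_equal(out_w + g$end_w, g$support)
  # topo order is a valid permutation respecting all edges
  expect_setequal(g$topo, 0:(n - 1))
  pos <- integer(n)
  pos[g$topo + 1] <- seq_len(n)
  expect_true(all(pos[g$edge_from + 1] < pos[g$edge_to + 1]))
}

test_that("aligning to a graph reproduces pairwise scores and paths", {
  g <- build_graph("ACGT")
  a <- align_to_graph(g, "ACGT")
  expect_equal(a$score, 8)
  expect_equal(sum(!is.na(a$path$node) & !is.na(a$path$qpos)), 4)

  expect_equal(align_to_graph(g, "ACTT")$score, 4)   # 3 matches, 1 mismatch
  expect_equal(align_to_graph(g, "AGT")$score, 2)    # 3 matches, affine open -4

  empty <- poa_graph()
  tr <- align_to_graph(empty, "ACG")
  expect_equal(nrow(tr$path), 3)
  expect_true(all(is.na(tr$path$node)))
  expect_error(align_to_graph(g, ""), "empty")
})

test_that("adding sequences updates support, nodes and edge weights", {
  g <- build_graph(c("ACGT", "ACGT"))
  expect_equal(poa_size(g), 4)
  expect_equal(g$support, rep(2L, 4))
  check_graph_invariants(g)

  g2 <- build_graph(c("ACGT", "ACTT"))
  expect_equal(poa_size(g2), 5)
  check_graph_invariants(g2)

  g3 <- build_graph("TTAG")
  expect_equal(poa_size(g3), 4)
  expect_equal(g3$support, rep(1L, 4))
  expect_equal(consensus_from_graph(g3), "TTAG")
})

test_that("consensus follows the majority through small graphs", {
  expect_equal(poa_consensus("ACGT"), "ACGT")
  expect_equal(poa_consensus(c("ACGT", "ACGT", "ACTT")), "ACGT")
  expect_equal(poa_consensus(c("ACGT", "AGT", "ACGT")), "ACGT")
  expect_error(poa_consensus(character(0)), "zero|empty")
  expect_error(consensus_from_graph(poa_graph()), "empty")
})

test_that("graph invariants hold throughout an incremental noisy build", {
  withr::local_seed(14)
  ref <- random_dna(60)
  g <- poa_graph()
  for (i in 1:8) {
    s <- mutate_reference(ref, 0.08, seed = i)
    g <- add_to_graph(g, s, align_to_graph(g, s))
    check_graph_invariants(g)
  }
})

test_that("identical sequences always yield themselves as consensus", {
  withr::local_seed(31)
  for (i in 1:20) {
    s <- random_dna(sample(4:60, 1))
    m <- sample(1:6, 1)
    expect_identical(poa_consensus(rep(s, m)), s)
  }
})

test_that("a strict majority of identical copies dominates near-identical variants", {
  withr::local_seed(77)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  while (n_checked < 60) {
    s <- random_dna(sample(3:8, 1))
    m <- sample(2:5, 1)
    n_major <- floor(m / 2) + 1
    variants <- as.character(replicate(m - n_major, {
      ch <- strsplit(s, "")[[1]]
      op <- sample(c("sub", "ins", "del"), 1)
      i <- sample(length(ch), 1)
      if (op == "sub") ch[i] <- sample(setdiff(bases, ch[i]), 1)
      else if (op == "ins") ch[i] <- paste0(ch[i], sample(bases, 1))
      else if (length(ch) > 1) ch <- ch[-i]
      paste(ch, collapse = "")
    }))
    stopifnot(all(adist(variants, s) <= 1))
    seqs <- sample(c(rep(s, n_major), variants))  # arbitrary order
    expect_identical(poa_consensus(seqs), s)
    n_checked <- n_checked + 1
  }
})

test_that("the consensus is a maximum-score start-to-end path", {
  withr::local_seed(55)
  for (i in 1:25) {
    base <- random_dna(sample(5:8, 1))
    seqs <- vapply(1:3, function(j) mutate_reference(base, 0.2, seed = i * 10 + j),
                   character(1))
    g <- build_graph(seqs)
    cons <- consensus_from_graph(g)
    paths <- ref_poa_paths(g)
    scores <- vapply(paths, function(p) p$score, numeric(1))
    best_strs <- vapply(paths[scores == max(scores)], function(p) p$str, character(1))
    expect_true(cons %in% best_strs)
  }
})
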