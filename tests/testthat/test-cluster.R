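test_that("minimizers match a brute-force window scan", {
  # homopolymer: one maximal run, reported once at its first position
  m <- minimizers("AAAAAA", k = 3, w = 2)
  expect_equal(m$kmer, "AAA")
  expect_equal(m$pos, 0)

  # k == nchar(seq): the single k-mer
  expect_equal(minimizers("ACGTT", k = 5, w = 3)$kmer, "ACGTT")
  expect_equal(nrow(minimizers("ACG", k = 5, w = 2)), 0)

  withr::local_seed(21)
  for (i in 1:30) {
    s <- random_dna(sample(20:120, 1))
    k <- sample(3:9, 1)
    w <- sample(2:12, 1)
    got <- unique(minimizers(s, k, w)$kmer)
    expect_setequal(got, ref_minimizer_kmers(s, k, w))
  }
})

test_that("reads sort by expected correct bases, then length, then id", {
  r <- make_reads(c(random_dna(100), random_dna(100)), q = 30)
  r$qual[[2]] <- rep(10L, 100)
  expect_equal(sort_reads_for_clustering(r)$id, c("r001", "r002"))

  # 200bp @ Q10 (expected correct 180) beats 100bp @ Q30 (99.9)
  r <- make_reads(c(random_dna(100), random_dna(200)))
  r$qual[[1]] <- rep(30L, 100)
  r$qual[[2]] <- rep(10L, 200)
  s <- sort_reads_for_clustering(r)
  expect_equal(s$id[1], "r002")
  expect_equal(s$exp_correct, c(180, 99.9), tolerance = 1e-6)

  r <- make_reads(c("ACGTACGT", "ACGTACGT"), ids = c("b", "a"))
  expect_equal(sort_reads_for_clustering(r)$id, c("a", "b"))
})

test_that("identical reads form one cluster; divergent references split", {
  reads <- make_reads(rep(random_reference(500, 3), 20))
  cl <- cluster_reads(reads)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 20)

  # two unrelated references (divergence far above 30%), error-free reads
  a <- random_reference(600, 10)
  b <- random_reference(600, 20)
  expect_lt(align_pair(a, b, mode = "global")$identity, 0.7)
  reads <- make_reads(c(rep(a, 20), rep(b, 20)))
  cl <- cluster_reads(reads)
  expect_equal(nrow(cl), 2)
  by_origin <- split(reads$id, rep(c("a", "b"), each = 20))
  expect_true(setequal(cl$member_ids[[1]], by_origin$a) ||
              setequal(cl$member_ids[[1]], by_origin$b))
  expect_error(cluster_reads(reads[0, ]), "no reads")
})

test_that("noisy two-strand reads form strand-split clusters covering most reads", {
  ref <- random_reference(700, 42)
  sim <- simulate_reads(c(truth = ref), 300, strand_prob = 0.5, seed = 42)
  cl <- cluster_reads(sim$reads)
  expect_gte(nrow(cl), 2)
  top2 <- sum(sort(cl$size, decreasing = TRUE)[1:2])
  expect_gte(top2 / nrow(sim$reads), 0.9)
})

test_that("clustering is a partition and invariant to input order", {
  ref <- random_reference(400, 8)
  sim <- simulate_reads(c(x = ref), 40, strand_prob = 0, seed = 9)
  cl <- cluster_reads(sim$reads)
  ids <- unlist(cl$member_ids)
  expect_setequal(ids, sim$reads$id)
  expect_equal(anyDuplicated(ids), 0)
  expect_true(all(mapply(function(r, m) r %in% m, cl$representative_id, cl$member_ids)))

  withr::local_seed(1)
  perm <- sample(nrow(sim$reads))
  cl2 <- cluster_reads(sim$reads[perm, ])
  expect_equal(cl2$representative_id, cl$representative_id)
  expect_equal(cl2$member_ids, cl$member_ids)
})

test_that("lowering the shared-fraction threshold never increases cluster count", {
  ref <- random_reference(500, 5)
  sim <- simulate_reads(c(x = ref), 60, strand_prob = 0.5, seed = 6)
  counts <- vapply(c(0.05, 0.12, 0.3, 0.6, 0.9),
                   function(t) nrow(cluster_reads(sim$reads, shared_fraction_threshold = t)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))

  # error-free identical reads collapse to one cluster at any threshold <= 1
  reads <- make_reads(rep(random_reference(300, 2), 10))
  for (t in c(0.1, 0.5, 1)) {
    expect_equal(nrow(cluster_reads(reads, shared_fraction_threshold = t)), 1)
  }
})
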