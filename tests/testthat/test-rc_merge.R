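two_strand_records <- function(len = 400, n_reads = 50, seed = 12) {
  s <- random_reference(len, seed)
  consensus_records(
    consensus_id = c("c1", "c2"),
    seq = c(s, reverse_complement(s)),
    cluster_ids = list(1L, 2L),
    supporting_read_ids = list(sprintf("f%02d", 1:n_reads), sprintf("r%02d", 1:n_reads))
  )
}

test_that("reverse-complement duplicates merge and pool their reads", {
  recs <- two_strand_records()
  m <- merge_duplicate_consensuses(recs)
  expect_equal(nrow(m), 1)
  expect_equal(length(m$supporting_read_ids[[1]]), 100)
  expect_setequal(m$cluster_ids[[1]], c(1L, 2L))
  # reads of the merged-away opposite-strand member are flagged for flipping
  expect_equal(sort(m$flipped_read_ids[[1]]), sprintf("r%02d", 1:50))
  expect_gt(length(attr(m, "merge_log")), 0)
})

test_that("pairs below the identity threshold are retained unchanged", {
  s <- random_reference(500, 31)
  other <- mutate_reference(s, 0.2, seed = 32)
  id <- best_orientation_identity(s, other)$identity
  expect_lt(id, 0.9)
  recs <- consensus_records(c("a", "b"), c(s, other), list(1L, 2L),
                            list("x1", "x2"))
  m <- merge_duplicate_consensuses(recs)
  expect_equal(nrow(m), 2)
  expect_equal(m$seq, recs$seq)
})

test_that("transitive components collapse into one record", {
  seed_seq <- random_reference(700, 44)
  copies <- vapply(1:3, function(i) mutate_reference(seed_seq, 0.01, seed = 44 + i),
                   character(1))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(best_orientation_identity(copies[i], copies[j])$identity, 0.9)
  }
  recs <- consensus_records(c("a", "b", "c"), copies, list(1L, 2L, 3L),
                            list(c("r1", "r2", "r3"), c("r4", "r5"), "r6"))
  m <- merge_duplicate_consensuses(recs)
  expect_equal(nrow(m), 1)
  expect_setequal(m$supporting_read_ids[[1]], sprintf("r%d", 1:6))
  # survivor is the member with the most supporting reads
  expect_equal(m$consensus_id, "a")
})

test_that("merging conserves reads, is idempotent and threshold-monotone", {
  recs <- two_strand_records(seed = 77)
  extra <- consensus_records("c3", random_reference(400, 99), list(3L),
                             list(sprintf("z%02d", 1:10)))
  all_recs <- dplyr::bind_rows(recs, extra)
  m1 <- merge_duplicate_consensuses(all_recs)
  expect_lte(nrow(m1), nrow(all_recs))
  expect_setequal(unlist(m1$supporting_read_ids), unlist(all_recs$supporting_read_ids))

  m2 <- merge_duplicate_consensuses(m1)
  expect_equal(m2$seq, m1$seq)
  expect_equal(m2$supporting_read_ids, m1$supporting_read_ids)

  lo <- merge_duplicate_consensuses(all_recs, identity_threshold = 0.5)
  hi <- merge_duplicate_consensuses(all_recs, identity_threshold = 0.99)
  expect_lte(nrow(lo), nrow(hi))

  empty <- merge_duplicate_consensuses(all_recs[0, ])
  expect_equal(nrow(empty), 0)
})
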