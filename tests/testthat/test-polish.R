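plant_substitutions <- function(seq, n, seed) {
  ch <- strsplit(seq, "")[[1]]
  idx <- withr::with_seed(seed, sample(length(ch), n))
  for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  paste(ch, collapse = "")
}

test_that("reads map back to the draft on the correct strand", {
  draft <- random_reference(300, 1)
  reads <- make_reads(c(draft, reverse_complement(draft)))
  m <- map_reads_to_draft(reads, draft)
  expect_equal(m$identity, c(1, 1))
  expect_equal(m$orientation, c("forward", "reverse_complement"))
  expect_equal(m$cigar, c("300M", "300M"))

  junk <- make_reads(random_reference(300, 999))
  m2 <- map_reads_to_draft(junk, draft)
  expect_equal(nrow(m2), 0)
  expect_equal(attr(m2, "dropped"), "r001")
  expect_error(map_reads_to_draft(reads, ""), "empty")
})

test_that("polishing unanimous reads is the identity operation", {
  draft <- random_reference(650, 2)
  reads <- make_reads(rep(draft, 30))
  expect_identical(polish_once(draft, reads), draft)
})

test_that("one round corrects a planted substitution with perfect reads", {
  truth <- random_reference(700, 3)
  draft <- plant_substitutions(truth, 1, seed = 50)
  reads <- make_reads(rep(truth, 50))
  expect_identical(polish_once(draft, reads), truth)
})

test_that("coverage below the window floor keeps the draft", {
  truth <- random_reference(400, 4)
  draft <- plant_substitutions(truth, 3, seed = 51)
  reads <- make_reads(rep(truth, 2))  # < min_window_coverage = 3
  expect_identical(polish_once(draft, reads), draft)
  expect_warning(out <- polish_once(draft, make_reads(random_reference(400, 5))),
                 "no reads mapped")
  expect_identical(out, draft)
})

test_that("polish applies rounds, early-stops and reports the count", {
  truth <- random_reference(500, 6)
  draft <- plant_substitutions(truth, 5, seed = 52)
  reads <- make_reads(rep(truth, 40))

  p0 <- polish(draft, reads, rounds = 0)
  expect_identical(p0$seq, draft)
  expect_equal(p0$polished_rounds, 0)

  # perfect reads equal to the draft: the first round changes nothing
  p1 <- polish(truth, reads, rounds = 2)
  expect_identical(p1$seq, truth)
  expect_equal(p1$polished_rounds, 1)

  p2 <- polish(draft, reads, rounds = 2)
  expect_identical(p2$seq, truth)
})

test_that("polishing noisy simulated reads does not degrade the draft", {
  draft_acc <- numeric(8)
  polish_acc <- numeric(8)
  for (i in 1:8) {
    ref <- random_reference(500, 600 + i)
    sim <- simulate_reads(c(x = ref), 60, strand_prob = 0, seed = 600 + i)
    draft <- poa_consensus(sim$reads$seq[1:20])
    p <- polish(draft, sim$reads, rounds = 1)
    draft_acc[i] <- evaluate_accuracy(draft, ref)
    polish_acc[i] <- evaluate_accuracy(p$seq, ref)
    # splicing sanity: length stays within 10% of the draft
    expect_lt(abs(nchar(p$seq) - nchar(draft)) / nchar(draft), 0.1)
  }
  expect_gte(median(polish_acc), median(draft_acc))
  expect_gte(sum(polish_acc >= draft_acc), 6)
})
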