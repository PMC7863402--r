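test_that("random references are seeded and mutually divergent", {
  expect_equal(nchar(random_reference(1, 5)), 1)
  expect_identical(random_reference(700, 5), random_reference(700, 5))
  withr::local_seed(2)
  seeds <- matrix(sample(1e6, 40), ncol = 2)
  for (i in seq_len(20)) {
    a <- random_reference(400, seeds[i, 1])
    b <- random_reference(400, seeds[i, 2])
    expect_lt(align_pair(a, b, mode = "global")$identity, 0.75)
  }
})

test_that("mutate_reference realizes approximately the requested divergence", {
  ref <- random_reference(700, 33)
  expect_identical(mutate_reference(ref, 0), ref)
  id15 <- align_pair(ref, mutate_reference(ref, 0.15, seed = 34), mode = "global")$identity
  expect_gte(id15, 0.80)
  expect_lte(id15, 0.90)
  # at high divergence the optimal alignment recovers chance matches, so the
  # realized identity sits above 1 - divergence but far below the 0.15 band
  id50 <- align_pair(ref, mutate_reference(ref, 0.5, seed = 35), mode = "global")$identity
  expect_lt(id50, 0.70)
  expect_lt(id50, id15 - 0.1)
})

test_that("error-free simulation reproduces the reference exactly", {
  ref <- random_reference(500, 40)
  sim <- simulate_reads(c(x = ref), 5, mean_error_rate = 0, per_read_sd = 0,
                        strand_prob = 0, seed = 41)
  expect_true(all(sim$reads$seq == ref))
  expect_true(all(sim$truth$strand == "forward"))
})

test_that("strand assignment is Bernoulli(strand_prob)", {
  ref <- random_reference(300, 42)
  sim <- simulate_reads(c(x = ref), 300, strand_prob = 0.5, seed = 43)
  n_rc <- sum(sim$truth$strand == "reverse_complement")
  expect_lt(abs(n_rc - 150), 3 * sqrt(300 * 0.25))
})

test_that("realized error rates track the error model", {
  ref <- random_reference(500, 44)
  sim <- simulate_reads(c(x = ref), 60, strand_prob = 0, seed = 45)
  d <- vapply(sim$reads$seq[1:40], function(s) {
    a <- align_pair(ref, s, mode = "global")
    1 - a$matches / a$alignment_length
  }, numeric(1))
  expect_gte(mean(d), 0.05)
  expect_lte(mean(d), 0.09)
  # quality strings encode the drawn per-read rate
  expect_equal(
    vapply(sim$reads$qual[1:10], function(q) q[1], numeric(1)),
    pmax(1, pmin(93, round(-10 * log10(sim$truth$error_rate[1:10]))))
  )
})

test_that("simulation is fully reproducible under a seed", {
  ref <- random_reference(300, 46)
  s1 <- simulate_reads(c(x = ref), 20, seed = 47)
  s2 <- simulate_reads(c(x = ref), 20, seed = 47)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("primers are attached before corruption and contaminants are labeled", {
  ref <- random_reference(300, 48)
  fwd <- "ACRGTACGTTAGCATYGCAT"
  rev <- "TGCAYTAGCTAGGTWCCAGT"
  sim <- simulate_reads(c(x = ref), 10, mean_error_rate = 0, per_read_sd = 0,
                        strand_prob = 0, primers = list(fwd = fwd, rev = rev),
                        seed = 49)
  expect_true(all(nchar(sim$reads$seq) == 300 + 40))
  first20 <- strsplit(substr(sim$reads$seq[1], 1, 20), "")[[1]]
  pat <- strsplit(fwd, "")[[1]]
  expect_true(all(mapply(iupac_match, first20, pat)))

  simc <- simulate_reads(c(x = ref), 20, contaminant_fraction = 0.2, seed = 50)
  expect_equal(sum(simc$truth$ref_name == "contaminant"), 4)
})

test_that("the accuracy metric matches the conventional percent format", {
  x <- random_reference(300, 51)
  expect_equal(evaluate_accuracy(x, x), 1)

  truth <- random_reference(726, 52)
  ch <- strsplit(truth, "")[[1]]
  idx <- withr::with_seed(53, sample(726, 10))
  for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  cons <- paste(ch, collapse = "")
  expect_equal(evaluate_accuracy(cons, truth), (726 - 10) / 726)
  expect_equal(format_accuracy(cons, truth), "98.6% (10/726)")

  perfect <- random_reference(709, 54)
  expect_equal(format_accuracy(perfect, perfect), "100% (0/709)")
})
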