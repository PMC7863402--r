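test_that("iupac_match expands ambiguity codes and treats N permissively", {
  expect_true(iupac_match("A", "R"))
  expect_false(iupac_match("C", "R"))
  expect_true(iupac_match("N", "Y"))
  expect_true(iupac_match("T", "N"))
  expect_error(iupac_match("A", "Q"), "IUPAC")
  expect_error(iupac_match("R", "A"), "not in")
})

test_that("read_primers normalizes U and validates the alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">fwd primer", "ACRGUU", ">rev", "TTYGCA"), f)
  p <- read_primers(f)
  expect_equal(p$name, c("fwd", "rev"))
  expect_equal(p$seq[1], "ACRGTT")
  writeLines(c(">bad", "ACXGT"), f)
  expect_error(read_primers(f), "non-IUPAC")
})

test_that("find_primer locates exact and reverse-complement placements", {
  withr::local_seed(61)
  primer <- "ACGTACGTTAGCATTGCATG"   # 20 nt
  body <- random_dna(400)
  cons <- paste0(primer, body)
  h <- find_primer(cons, primer, "p")
  expect_equal(h$start, 0)
  expect_equal(h$edits, 0)
  expect_equal(h$strand, "forward")
  expect_equal(h$consensus_end, "5prime")

  cons3 <- paste0(body, reverse_complement(primer))
  h3 <- find_primer(cons3, primer, "p")
  expect_equal(h3$end, nchar(cons3))
  expect_equal(h3$strand, "reverse_complement")
  expect_equal(h3$edits, 0)
})

test_that("edit-tolerant search agrees with a brute-force occurrence oracle", {
  withr::local_seed(62)
  primer <- random_dna(20)
  mutated <- plant <- strsplit(primer, "")[[1]]
  idx <- sample(20, 2)
  for (i in idx) plant[i] <- setdiff(c("A", "C", "G", "T"), plant[i])[1]
  cons <- paste0(random_dna(10), paste(plant, collapse = ""), random_dna(670))
  h <- find_primer(cons, primer, "p", max_edit_fraction = 0.20)  # allow 4
  expect_equal(h$edits, 2)
  expect_equal(h$edits, ref_best_occurrence_edits(substr(cons, 1, 150), primer))

  expect_warning(none <- find_primer("ACGTACGT", primer, "p", window = 10),
                 "window")
  expect_null(none)
})

test_that("trim_primers returns the insert between both primer hits", {
  withr::local_seed(63)
  fwd <- "ACRGTACGTTAGCATYGCAT"
  rev <- "TGCAYTAGCTAGGTWCCAGT"
  primers <- tibble::tibble(name = c("fwd", "rev"), seq = c(fwd, rev))
  insert <- random_dna(500)
  cons <- paste0(chartr("RY", "AC", fwd), insert,
                 reverse_complement(chartr("YW", "CA", rev)))
  tr <- trim_primers(cons, primers)
  expect_equal(tr$trimmed, insert)
  expect_equal(nrow(tr$hits), 2)
  expect_setequal(tr$hits$consensus_end, c("5prime", "3prime"))

  # idempotence: a trimmed consensus has no further hits
  tr2 <- trim_primers(tr$trimmed, primers)
  expect_equal(nrow(tr2$hits), 0)
  expect_equal(tr2$trimmed, insert)

  # 5' only
  cons5 <- paste0(chartr("RY", "AC", fwd), insert)
  tr5 <- trim_primers(cons5, primers)
  expect_equal(tr5$trimmed, insert)
  expect_equal(tr5$hits$consensus_end, "5prime")

  # no primers supplied
  expect_equal(trim_primers(cons, primers[0, ])$trimmed, cons)

  # trimming that would leave under 50 bases is skipped
  tiny <- paste0(chartr("RY", "AC", fwd), random_dna(20),
                 reverse_complement(chartr("YW", "CA", rev)))
  expect_warning(trt <- trim_primers(tiny, primers), "fewer than 50")
  expect_gte(nchar(trt$trimmed), 20)
})

test_that("trimmed output is always a contiguous substring", {
  withr::local_seed(64)
  primers <- tibble::tibble(name = "p", seq = random_dna(22))
  for (i in 1:10) {
    cons <- paste0(primers$seq, random_dna(300))
    tr <- trim_primers(cons, primers)
    expect_true(grepl(tr$trimmed, cons, fixed = TRUE))
  }
})

test_that("trim_and_rerun merges strand-split consensuses hidden by primer tails", {
  withr::local_seed(65)
  insert <- random_dna(300)
  pf <- random_dna(60); pr <- random_dna(60)
  pg <- random_dna(60); ph <- random_dna(60)
  primers <- tibble::tibble(name = c("f", "r", "g", "h"), seq = c(pf, pr, pg, ph))
  c1 <- paste0(pf, insert, reverse_complement(pr))
  c2 <- reverse_complement(paste0(pg, insert, reverse_complement(ph)))
  pre <- best_orientation_identity(c1, c2)$identity
  expect_lt(pre, 0.9)
  reads <- make_reads(c(rep(c1, 6), rep(c2, 6)))
  recs <- consensus_records(c("a", "b"), c(c1, c2), list(1L, 2L),
                            list(reads$id[1:6], reads$id[7:12]))
  out <- trim_and_rerun(recs, reads, primers)
  expect_equal(nrow(out), 1)
  expect_equal(length(out$supporting_read_ids[[1]]), 12)
  expect_gt(length(attr(out, "rerun_log")), 0)
  expect_gte(nrow(attr(out, "primer_hits")), 2)
  # final sequence carries no remaining primer hit
  expect_equal(nrow(trim_primers(out$seq[[1]], primers)$hits), 0)
})

test_that("trim_and_rerun with no hits returns the input unchanged", {
  recs <- consensus_records("a", random_reference(300, 70), list(1L), list("r1"))
  reads <- make_reads(recs$seq[[1]], ids = "r1")
  primers <- tibble::tibble(name = "p", seq = random_reference(20, 71))
  out <- trim_and_rerun(recs, reads, primers)
  expect_equal(out$seq, recs$seq)
  expect_equal(nrow(attr(out, "primer_hits")), 0)
})
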