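test_that("Phred scores convert to error probabilities", {
  expect_equal(phred_to_error_prob(30), 0.001)
  expect_equal(phred_to_error_prob(c(10, 20)), c(0.1, 0.01))
})

one_locus_panel <- function(a = "C", b = "A") {
  panel_loci("rs1", "1", 1000L, a, b)
}

test_that("pileup match/mismatch symbols resolve against the reference", {
  panel <- one_locus_panel("C", "A")
  pp <- withr::local_tempfile()
  # 4 reference-matching calls (ref C) and 2 A calls, all Q40
  writeLines(pileup_line("1", 1000, "C", "..,,AA", rep(40, 6)), pp)
  counts <- count_from_pileup(pp, panel)
  expect_equal(counts$n_C, 4L)
  expect_equal(counts$n_A, 2L)
  expect_equal(counts$n_ambiguous, 0L)
  expect_equal(counts$depth_qualified, 6L)
})

test_that("base quality filtering is a strict >= threshold", {
  panel <- one_locus_panel("C", "A")
  pp <- withr::local_tempfile()
  # Q29 base excluded entirely at cutoff 30; Q30 base kept
  writeLines(pileup_line("1", 1000, "C", ".A.A", c(40, 29, 30, 30)), pp)
  counts <- count_from_pileup(pp, panel, min_base_quality = 30)
  expect_equal(counts$n_C, 2L)
  expect_equal(counts$n_A, 1L)
  expect_equal(counts$depth_qualified, 3L)
})

test_that("non-panel and N calls are counted as ambiguous only", {
  panel <- one_locus_panel("C", "A")
  pp <- withr::local_tempfile()
  writeLines(pileup_line("1", 1000, "C", ".AGTNt", rep(40, 6)), pp)
  counts <- count_from_pileup(pp, panel)
  expect_equal(counts$n_C, 1L)
  expect_equal(counts$n_A, 1L)
  expect_equal(counts$n_G, 0L)  # G is not a panel allele here
  expect_equal(counts$n_T, 0L)
  expect_equal(counts$n_ambiguous, 4L)
})

test_that("indel and read start/end markup never changes base counts", {
  panel <- one_locus_panel("C", "A")
  plain <- withr::local_tempfile()
  marked <- withr::local_tempfile()
  writeLines(pileup_line("1", 1000, "C", "..,,AA", rep(40, 6)), plain)
  # same 6 calls with read-start (^ + mapq), read-end, insertion, deletion
  writeLines(pileup_line("1", 1000, "C", "^F..$,+2AT,-1aAA$", rep(40, 6)),
             marked)
  expect_equal(count_from_pileup(plain, panel),
               count_from_pileup(marked, panel))
})

test_that("raising the quality cutoff never increases any count", {
  panel <- one_locus_panel("C", "A")
  pp <- withr::local_tempfile()
  set.seed(5)
  quals <- sample(10:45, 60, replace = TRUE)
  bases <- paste(sample(c(".", ",", "A", "G", "N"), 60, replace = TRUE),
                 collapse = "")
  writeLines(pileup_line("1", 1000, "C", bases, quals), pp)
  cols <- c("n_A", "n_C", "n_G", "n_T", "n_ambiguous", "depth_qualified")
  prev <- count_from_pileup(pp, panel, min_base_quality = 10)
  for (q in c(20, 30, 40, 46)) {
    cur <- count_from_pileup(pp, panel, min_base_quality = q)
    expect_true(all(unlist(cur[cols]) <= unlist(prev[cols])))
    prev <- cur
  }
})

test_that("panel loci absent from the pileup get zero counts and a flag", {
  panel <- make_test_panel()
  pp <- withr::local_tempfile()
  writeLines(pileup_line("1", 1000, "A", "....", rep(40, 4)), pp)
  expect_message(counts <- count_from_pileup(pp, panel), "absent")
  expect_equal(counts$absent, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(counts$depth_qualified[2:4], rep(0L, 3))
})

test_that("malformed pileups raise format errors with line numbers", {
  panel <- one_locus_panel()
  short <- withr::local_tempfile()
  writeLines(c(pileup_line("1", 1000, "C", "..", c(40, 40)),
               "1\t1001\tC\t5"), short)
  expect_error(count_from_pileup(short, panel), "line 2")

  mismatch <- withr::local_tempfile()
  writeLines("1\t1000\tC\t3\t...\tII", mismatch)
  expect_error(count_from_pileup(mismatch, panel), "mismatch.*line 1")
})

test_that("counts tables load, validate against the panel, and round-trip", {
  panel <- make_test_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tn_A\tn_C\tn_G\tn_T\tn_ambiguous",
               "rs1\t980\t0\t20\t0\t0",
               "rs2\t0\t500\t0\t500\t10"), path)
  counts <- load_counts_table(path, panel)
  expect_equal(counts$depth_qualified[counts$locus_id == "rs1"], 1000L)
  expect_true(all(counts$absent[counts$locus_id %in% c("rs3", "rsY")]))

  rt <- withr::local_tempfile(fileext = ".tsv")
  write_counts_table(counts, rt)
  back <- load_counts_table(rt, panel)
  cols <- c("locus_id", "n_A", "n_C", "n_G", "n_T", "n_ambiguous",
            "depth_qualified")
  expect_equal(back[cols], counts[cols])
})

test_that("invalid counts tables are rejected with informative errors", {
  panel <- make_test_panel()
  bad_id <- withr::local_tempfile()
  writeLines(c("locus_id\tn_A\tn_C\tn_G\tn_T\tn_ambiguous",
               "rs999\t1\t0\t0\t0\t0"), bad_id)
  expect_error(load_counts_table(bad_id, panel), "rs999")

  dup <- withr::local_tempfile()
  writeLines(c("locus_id\tn_A\tn_C\tn_G\tn_T\tn_ambiguous",
               "rs1\t1\t0\t0\t0\t0",
               "rs1\t2\t0\t0\t0\t0"), dup)
  expect_error(load_counts_table(dup, panel), "duplicated")

  neg <- withr::local_tempfile()
  writeLines(c("locus_id\tn_A\tn_C\tn_G\tn_T\tn_ambiguous",
               "rs1\t-1\t0\t0\t0\t0"), neg)
  expect_error(load_counts_table(neg, panel), "negative")
})
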