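test_that("detect_run finds clean, interrupted, and split runs", {
  runs <- detect_run("QQQQQQ", "Q")
  expect_length(runs, 1)
  expect_equal(runs[[1]]$count, 6)
  expect_equal(nrow(runs[[1]]$interruptions), 0)

  # interrupted run spans all 9 positions, counting 7 Q
  runs <- detect_run("QQHQQQPQQ", "Q", max_gap = 1)
  expect_length(runs, 1)
  expect_equal(runs[[1]]$start, 0)
  expect_equal(runs[[1]]$end, 9)
  expect_equal(runs[[1]]$count, 7)
  expect_equal(runs[[1]]$interruptions$offset, c(2, 6))
  expect_equal(runs[[1]]$interruptions$residue, c("H", "P"))
  # matches the brute-force enumeration of all valid windows
  want <- oracle_runs("QQHQQQPQQ", "Q")
  expect_length(want, 1)
  expect_equal(want[[1]]$count, 7)

  # a gap beyond tolerance splits the tract
  runs <- detect_run("QQGGGGGQQQ", "Q", max_gap = 1)
  expect_length(runs, 2)
  expect_equal(vapply(runs, `[[`, integer(1), "count"), c(2L, 3L))

  expect_length(detect_run("", "Q"), 0)
  expect_length(detect_run("GGGG", "Q"), 0)
  expect_length(detect_run("QGQGQG", "Q"), 0)   # no seed of 2
  expect_error(detect_run("QQ", "H"), "residue")
})

test_that("detect_run equals the brute-force window oracle", {
  set.seed(201)
  for (rep in 1:150) {
    s <- random_aa(25, alphabet = c("Q", "A", "H", "P", "G"))
    got <- detect_run(s, "Q", min_seed = 2, max_gap = 1,
                      max_interrupt_frac = 0.34)
    want <- oracle_runs(s, "Q", 2, 1, 0.34)
    expect_equal(length(got), length(want), info = s)
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$start, want[[k]]$start, info = s)
      expect_equal(got[[k]]$end, want[[k]]$end, info = s)
      expect_equal(got[[k]]$count, want[[k]]$count, info = s)
    }
  }
})

test_that("detect_run with max_gap 0 is a plain maximal-homopolymer scan", {
  set.seed(202)
  for (rep in 1:1000) {
    s <- random_aa(30, alphabet = c("Q", "A", "G", "E"))
    got <- detect_run(s, "Q", min_seed = 2, max_gap = 0)
    want <- oracle_homopolymer(s, "Q", min_seed = 2)
    expect_equal(length(got), length(want), info = s)
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$start, want[[k]]$start, info = s)
      expect_equal(got[[k]]$count, want[[k]]$count, info = s)
      expect_equal(nrow(got[[k]]$interruptions), 0, info = s)
    }
  }
})

test_that("removing interruption positions leaves a pure homopolymer", {
  set.seed(203)
  for (rep in 1:100) {
    s <- random_aa(30, alphabet = c("Q", "H", "P", "G"))
    for (run in detect_run(s, "Q")) {
      span <- strsplit(substr(s, run$start + 1, run$end), "")[[1]]
      if (nrow(run$interruptions)) span <- span[-(run$interruptions$offset + 1)]
      expect_true(all(span == "Q"))
      expect_length(span, run$count)
      # no interruption stretch exceeds max_gap = 1: offsets never adjacent
      if (nrow(run$interruptions) > 1) {
        expect_true(all(diff(sort(run$interruptions$offset)) >= 2))
      }
    }
  }
})

test_that("assemble_domain picks runs and spacer per the QA-order rule", {
  d <- make_domain(q = 31, a = 5)   # naked-mole-rat-like composition
  expect_equal(d$q_count, 31L)
  expect_equal(d$a_count, 5L)
  expect_equal(d$ratio, 6.2)
  expect_equal(d$spacer, "E")

  # polyA only (chondrichthyan-like): no Q run, ratio undefined
  d <- assemble_domain(extract_qa_region(
    list(seq = make_seq(q = 0, a = 4, spacer = ""))))
  expect_null(d$q_run)
  expect_equal(d$a_count, 4L)
  expect_true(is.na(d$ratio))
  expect_equal(classify_sequence(d), "PROTO")

  # two equal-count Q runs: the earlier one is chosen
  rec <- list(seq = paste0("MSDVS", "QQQQ", "GGGGG", "QQQQ", "E", "AAA",
                           "VPRLR"))
  d <- assemble_domain(extract_qa_region(rec))
  expect_equal(d$q_run$start, 0)
  expect_equal(d$q_count, 4L)

  # the A run is only sought downstream of the chosen Q run
  rec <- list(seq = paste0("MSDVS", "AAAA", "GG", "QQQQQ", "E", "AA",
                           "VPRLR"))
  d <- assemble_domain(extract_qa_region(rec))
  expect_equal(d$q_count, 5L)
  expect_equal(d$a_count, 2L)
  expect_true(d$a_run$start > d$q_run$end)
})

test_that("qa_ratio matches the published worked examples and inverts", {
  expect_equal(qa_ratio(31, 5), 6.2)
  expect_equal(round(qa_ratio(7, 16), 2), 0.44)
  expect_equal(qa_ratio(5, 5), 1.0)
  expect_true(is.na(qa_ratio(0, 5)))
  expect_true(is.na(qa_ratio(5, 0)))
  expect_error(qa_ratio(-1, 5), "non-negative")
  set.seed(204)
  for (rep in 1:25) {
    q <- sample(1:40, 1); a <- sample(1:40, 1)
    expect_equal(qa_ratio(q, a) * qa_ratio(a, q), 1)
  }
})

test_that("codon purity is the modal-codon fraction", {
  expect_equal(codon_purity(c("CAG", "CAG", "CAG", "CAG")), 1.0)
  expect_equal(codon_purity(c("CAG", "CAA", "CAG", "CAA")), 0.5)
  expect_equal(codon_purity("GCG"), 1.0)
  expect_error(codon_purity(character(0)), "at least one")
  expect_error(codon_purity(c("CA", "CAG")), "3 nucleotides")
})

test_that("CDS pairing is validated before purity is computed", {
  g <- generate_clade("teleost", 3, seed = 5)
  doms <- profile_records(g$proteins, g$cds)
  for (d in doms) {
    expect_true(d$purity_q >= 0 && d$purity_q <= 1)
    expect_true(d$purity_a >= 0 && d$purity_a <= 1)
  }
  # truncated CDS: length mismatch is an error naming the record
  bad_cds <- g$cds
  bad_cds$cds[1] <- substr(bad_cds$cds[1], 1, 9)
  expect_error(profile_records(g$proteins, bad_cds), g$proteins$id[1])
  # frameshifted pairing: codons no longer translate to the run residues
  bad2 <- g$cds
  bad2$cds[2] <- paste0("TTT", substr(bad2$cds[2], 1, nchar(bad2$cds[2]) - 3))
  expect_error(profile_records(g$proteins, bad2), "translate")
})

test_that("assemble_domain is deterministic in its table rendering", {
  g <- generate_clade("anuran", 8, seed = 42)
  t1 <- domain_table(profile_records(g$proteins, g$cds))
  t2 <- domain_table(profile_records(g$proteins, g$cds))
  expect_identical(t1, t2)
})
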