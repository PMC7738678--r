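test_that("caecilian preset yields 2 Q and 3-5 A in every extracted domain", {
  g <- generate_clade("caecilian", 10, seed = 1)
  ct <- classify_table(profile_records(g$proteins))
  expect_true(all(ct$q_count == 2))
  expect_true(all(ct$a_count >= 3 & ct$a_count <= 5))
  expect_true(all(ct$class == "PRIMITIVE"))
})

test_that("purity 1 presets produce fully pure run codons", {
  p <- clade_preset("pure", c(6, 6), c(6, 6), purity = 1.0)
  g <- generate_clade(p, 5, seed = 3)
  doms <- profile_records(g$proteins, g$cds)
  for (d in doms) {
    expect_equal(d$purity_q, 1.0)
    expect_equal(d$purity_a, 1.0)
  }
  # low purity presets measurably reduce modal-codon fraction of the Q run
  lo <- clade_preset("lowpure", c(20, 20), c(6, 6), purity = 0.5)
  g2 <- generate_clade(lo, 10, seed = 3)
  pq <- vapply(profile_records(g2$proteins, g2$cds), `[[`, numeric(1),
               "purity_q")
  expect_lt(mean(pq), 0.85)
})

test_that("generation is byte-identical per seed and varies across seeds", {
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  write_protein_fasta(generate_clade("anolis", 8, seed = 9)$proteins, f1)
  write_protein_fasta(generate_clade("anolis", 8, seed = 9)$proteins, f2)
  write_protein_fasta(generate_clade("anolis", 8, seed = 10)$proteins, f3)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))
  unlink(c(f1, f2, f3))
})

test_that("impossible presets are rejected", {
  expect_error(clade_preset("bad", c(5, 3), c(2, 2)), "impossible preset")
  expect_error(clade_preset("bad", c(2, 50), c(2, 2)), "\\[0, 40\\]")
  expect_error(generate_clade("nosuch", 3), "unknown preset")
})

test_that("every built-in preset recovers its count bounds end to end", {
  for (p in clade_presets()) {
    g <- generate_clade(p, 12, seed = 17)
    ct <- classify_table(profile_records(g$proteins, g$cds))
    qr <- p$q_len_range; ar <- p$a_len_range
    if (qr[2] > 0) {
      expect_true(all(ct$q_count >= qr[1] & ct$q_count <= qr[2]),
                  info = p$name)
    } else {
      expect_true(all(ct$q_count == 0), info = p$name)
    }
    expect_true(all(ct$a_count >= ar[1] & ct$a_count <= ar[2]),
                info = p$name)
    expect_false(any(ct$class == "ABSENT"), info = p$name)
  }
})

test_that("slippage with zero rate is the identity on any tree", {
  dt <- vertebrate_toy_tree()
  out <- simulate_slippage(dt, 12, 5, slippage_params(base_rate = 0),
                           seed = 1)
  expect_true(all(out$q_count == 12))
  expect_true(all(out$a_count == 5))
})

test_that("pure expansion bias matches the analytic mean growth", {
  # single 100-Ma branch: E[leaf] = root + rate*len * E[step]
  phy <- ape::read.tree(text = "(A:100,B:100);")
  params <- slippage_params(base_rate = 0.05, expansion_bias = 1,
                            step_mean = 2)
  qs <- vapply(1:1000, function(s) {
    simulate_slippage(phy, 5, 5, params, seed = s)$q_count[1]
  }, numeric(1))
  expected <- 5 + 0.05 * 100 * 2
  se <- sd(qs) / sqrt(length(qs))
  expect_lt(abs(mean(qs) - expected), 3 * se)
  expect_true(all(qs >= 5))  # expansion-only never shrinks
})

test_that("symmetric slippage is a martingale away from the zero floor", {
  phy <- ape::read.tree(text = "((A:50,B:50):25,C:75);")
  params <- slippage_params(base_rate = 0.02, expansion_bias = 0.5)
  leaves <- vapply(1:1000, function(s) {
    mean(simulate_slippage(phy, 15, 15, params, seed = s)$q_count)
  }, numeric(1))
  se <- sd(leaves) / sqrt(length(leaves))
  expect_lt(abs(mean(leaves) - 15), 3 * se)
})

test_that("leaf-count variance grows with the slippage rate", {
  phy <- ape::read.tree(text = "(A:100,B:100);")
  vars <- vapply(c(0.01, 0.05, 0.2), function(rate) {
    params <- slippage_params(base_rate = rate)
    qs <- vapply(1:400, function(s) {
      simulate_slippage(phy, 20, 20, params, seed = 10000 + s)$q_count[1]
    }, numeric(1))
    var(qs)
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("purity coupling raises the effective event rate", {
  phy <- ape::read.tree(text = "(A:200,B:200);")
  base <- slippage_params(base_rate = 0.02, expansion_bias = 1)
  coupled <- slippage_params(base_rate = 0.02, expansion_bias = 1,
                             purity_coupling = 2, purity = 1)
  g1 <- mean(vapply(1:300, function(s)
    simulate_slippage(phy, 5, 5, base, seed = s)$q_count[1], numeric(1)))
  g2 <- mean(vapply(1:300, function(s)
    simulate_slippage(phy, 5, 5, coupled, seed = s)$q_count[1], numeric(1)))
  expect_gt(g2, g1)
})
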