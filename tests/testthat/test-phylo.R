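test_that("fitch reconstruction matches hand-worked small cases", {
  # balanced 4-leaf split: one change, VARIABLE originates at its MRCA
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rep4 <- fitch_reconstruct(phy, c(A = "PROTO", B = "PROTO",
                                   C = "VARIABLE", D = "VARIABLE"))
  expect_equal(rep4$changes, 1L)
  ov <- rep4$origins[rep4$origins$class == "VARIABLE", ]
  expect_equal(nrow(ov), 1)
  expect_equal(ov$node, ape::getMRCA(phy, c("C", "D")))
  # exhaustive check of the minimum
  ls <- c(A = 2L, B = 2L, C = 4L, D = 4L)
  expect_equal(oracle_parsimony(phy, ls), 1)

  # uniform states: zero changes, origin at the root
  rep0 <- fitch_reconstruct(phy, c(A = "PRIMITIVE", B = "PRIMITIVE",
                                   C = "PRIMITIVE", D = "PRIMITIVE"))
  expect_equal(rep0$changes, 0L)
  expect_equal(rep0$origins$node, 5L)  # ape root = ntip + 1
  expect_true(is.infinite(rep0$origins$parent_age))

  # star tree {A,A,B}: iterated pairwise rule gives 1 change
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  reps <- fitch_reconstruct(star, c(t1 = "PROTO", t2 = "PROTO",
                                    t3 = "PRIMITIVE"))
  expect_equal(reps$changes, 1L)
  expect_equal(unname(reps$node_states[4]), "PROTO")  # majority at root
  expect_equal(oracle_parsimony(star, c(t1 = 2L, t2 = 2L, t3 = 3L)), 1)
})

test_that("fitch changes equal the exhaustive minimum on a 5-leaf tree", {
  phy <- five_leaf_tree()
  classes <- repeat_classes()
  tips <- phy$tip.label
  grid <- expand.grid(rep(list(1:4), 5))
  for (g in seq_len(nrow(grid))) {
    st <- as.integer(grid[g, ])
    got <- fitch_reconstruct(phy, setNames(classes[st], tips))$changes
    want <- oracle_parsimony(phy, setNames(st, tips))
    if (got != want) {
      fail(sprintf("pattern %s: fitch %d, exhaustive %d",
                   paste(st, collapse = ""), got, want))
    }
  }
  succeed()
})

test_that("leaf relabeling consistent with topology preserves change counts", {
  phy <- five_leaf_tree()
  classes <- repeat_classes()
  set.seed(301)
  for (rep in 1:25) {
    st <- sample(1:4, 5, replace = TRUE)
    states <- setNames(classes[st], phy$tip.label)
    base <- fitch_reconstruct(phy, states)$changes
    # swap the cherry (A,B): an automorphism of the caterpillar topology
    swapped <- states
    swapped[c("A", "B")] <- states[c("B", "A")]
    expect_equal(fitch_reconstruct(phy, swapped)$changes, base)
  }
})

test_that("ordered (Wagner) mode never undercounts unordered Fitch", {
  phy <- five_leaf_tree()
  classes <- repeat_classes()
  set.seed(302)
  for (rep in 1:50) {
    st <- sample(1:4, 5, replace = TRUE)
    states <- setNames(classes[st], phy$tip.label)
    unord <- fitch_reconstruct(phy, states, ordered = FALSE)$changes
    ord <- fitch_reconstruct(phy, states, ordered = TRUE)$changes
    expect_true(ord >= unord)
    # the ordered cost equals its own exhaustive minimum
    expect_equal(ord, oracle_parsimony(phy, setNames(st, phy$tip.label),
                                       ordered = TRUE))
  }
})

test_that("fitch agrees with phangorn's parsimony scores", {
  skip_if_not_installed("phangorn")
  set.seed(303)
  classes <- repeat_classes()
  for (rep in 1:20) {
    phy <- ape::rtree(7)
    st <- sample(1:4, 7, replace = TRUE)
    states <- setNames(classes[st], phy$tip.label)
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(phy$tip.label, NULL)),
                            type = "USER", levels = classes)
    expect_equal(fitch_reconstruct(phy, states)$changes,
                 as.integer(phangorn::parsimony(phy, dat)))
  }
})

test_that("missing or unknown leaf states are hard errors", {
  phy <- five_leaf_tree()
  expect_error(fitch_reconstruct(phy, c(A = "PROTO")), "B.*C.*D.*E")
  expect_error(fitch_reconstruct(phy, setNames(rep("WOBBLY", 5),
                                               phy$tip.label)),
               "unknown state")
})

test_that("emergence ages read stem intervals off the dated toy tree", {
  dt <- vertebrate_toy_tree()
  report <- fitch_reconstruct(dt, vertebrate_toy_states())
  expect_equal(report$changes, 2L)
  ages <- emergence_ages(report)
  v <- ages[ages$class == "VARIABLE", ]
  expect_equal(v$lower_ma, 312)
  expect_equal(v$upper_ma, 350)
  p <- ages[ages$class == "PRIMITIVE", ]
  expect_equal(p$lower_ma, 430)
  expect_equal(p$upper_ma, 460)
  r <- ages[ages$class == "PROTO", ]
  expect_equal(r$label, ">460")
  expect_true(is.infinite(r$upper_ma))
  expect_false(any(ages$convergent))
})

test_that("independent origins of a class are both listed and flagged", {
  # PROTO twice on opposite sides of the root; brute force confirms 2 gains
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = "PROTO", B = "PRIMITIVE", C = "PRIMITIVE", D = "PROTO")
  expect_equal(oracle_parsimony(phy, c(A = 2L, B = 3L, C = 3L, D = 2L)), 2)
  report <- fitch_reconstruct(phy, states)
  expect_equal(report$changes, 2L)
  # ancestors resolve to the ordinally lower PROTO, so the derived
  # PRIMITIVE state is gained twice independently (once per cherry)
  op <- report$origins[report$origins$class == "PRIMITIVE", ]
  expect_equal(nrow(op), 2)
  expect_true(all(op$convergent))
  expect_setequal(op$label, c("B", "C"))
  ages <- emergence_ages(report)
  expect_equal(sum(ages$class == "PRIMITIVE"), 2)
})

test_that("classes absent from all leaves are omitted with a note", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  report <- fitch_reconstruct(phy, c(A = "PROTO", B = "PROTO",
                                     C = "PROTO", D = "PROTO"))
  expect_message(ages <- emergence_ages(report), "ABSENT")
  expect_equal(ages$class, "PROTO")
})
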