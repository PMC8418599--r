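test_that("the six distinguishing invariants are as printed", {
  g <- builtin_invariants()
  expect_length(g, 6L)
  expect_equal(length(g$g2$terms), 2L)
  expect_true(all(vapply(g$g2$terms, function(t) length(t$vars) == 1L, TRUE)))
  expect_equal(length(g$g3$terms), 6L)
  expect_true(all(vapply(g$g3$terms, function(t) length(t$vars) == 3L, TRUE)))
  expect_equal(length(g$g1$terms), 2L)
  expect_equal(length(g$g4$terms), 4L)
  expect_true(all(vapply(g$g4$terms, function(t) length(t$vars) == 4L, TRUE)))
  # every pattern variable lies on the zero group-sum support
  for (gi in g) {
    for (t in gi$terms) {
      expect_true(all(vapply(t$vars, group_sum, 1L) == 0L))
    }
  }
})

test_that("evaluation agrees with an independent evaluator and is exact on simple points", {
  g <- builtin_invariants()
  all_ones <- tibble::tibble(pattern = seminet:::pattern_strings(4L), q = 1)
  expect_equal(evaluate_qpoly(g$g1, all_ones), 0)

  q_eq <- all_ones
  q_eq$q[q_eq$pattern == "CTTC"] <- 0.375
  q_eq$q[q_eq$pattern == "GCGC"] <- 0.375
  expect_equal(evaluate_qpoly(g$g2, q_eq), 0)

  set.seed(12)
  for (gi in g) {
    qr <- tibble::tibble(pattern = seminet:::pattern_strings(4L),
                         q = sample(seq(-8, 8), 256, replace = TRUE) / 16)
    expect_equal(evaluate_qpoly(gi, qr), eval_qpoly_by_hand(gi, qr))
  }

  expect_error(evaluate_qpoly(g$g1, q_eq[1:10, ]), "variables")
})

test_that("permuting leaves acts on invariants compatibly with relabeling networks", {
  # g2 vanishes exactly on the quartet tree ab|cd under JC; relabeling
  # the network by taxon i -> taxon p(i) maps its ideal to the ideal of
  # the relabelled network via the inverse position permutation
  g2 <- builtin_invariants()$g2
  net <- quartet_tree("a", "b", "c", "d")
  tx <- taxa(net)
  expect_true(vanishes_on(g2, net, "JC", method = "symbolic")$vanishes)
  for (p in list(c(1L, 3L, 2L, 4L), c(2L, 1L, 4L, 3L), c(4L, 3L, 2L, 1L))) {
    relab <- relabel_network(net, setNames(tx[p], tx))
    gp <- seminet:::permute_qpoly(g2, order(p))
    expect_true(vanishes_on(gp, relab, "JC", method = "symbolic")$vanishes)
  }
})

test_that("invariants vanish at model points of the varieties they belong to", {
  # numerical membership sanity: evaluate at transform(site-pattern
  # distribution) for random exact parameters on a network where the
  # symbolic verdict is 'vanishes'
  g <- builtin_invariants()
  tri_ab <- cycle_network(list(c("a", "b"), "c", "d"), ret_block = 1L)
  expect_true(vanishes_on(g$g1, tri_ab, "K3P", method = "symbolic")$vanishes)
  for (s in 1:10) {
    params <- random_exact_params(tri_ab, "K3P", seed = 900 + s)
    q <- fourier_transform(site_pattern_distribution(tri_ab, params))
    expect_equal(evaluate_qpoly(g$g1, q), 0)
  }
  tree <- quartet_tree("a", "b", "c", "d")
  expect_true(vanishes_on(g$g2, tree, "JC", method = "symbolic")$vanishes)
  for (s in 1:10) {
    params <- random_exact_params(tree, "JC", seed = 950 + s)
    q <- fourier_transform(site_pattern_distribution(tree, params))
    expect_equal(evaluate_qpoly(g$g2, q), 0)
  }
})
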