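test_that("symbolic and modular vanishing verdicts agree", {
  g <- builtin_invariants()
  nets <- list(
    quartet_tree("a", "b", "c", "d"),
    cycle_network(list(c("a", "b"), "c", "d"), ret_block = 1L),
    cycle_network(list("a", "b", "c", "d"), ret_block = 3L),
    seminet:::double_triangle_network(c("a", "b"), c("c", "d"), "a", "c")
  )
  for (net in nets) {
    for (gi in g[c("g1", "g2", "g3")]) {
      for (con in c("JC", "K2P", "K3P")) {
        sym <- vanishes_on(gi, net, con, method = "symbolic")
        mod <- vanishes_on(gi, net, con, method = "modular")
        expect_equal(sym$vanishes, mod$vanishes)
        if (!mod$vanishes) {
          expect_true(is.finite(mod$witness_value) && mod$witness_value != 0)
        }
      }
    }
  }
})

test_that("g1 isolates a single triangle skeleton under K2P and K3P", {
  g1 <- builtin_invariants()$g1
  cat4 <- enumerate_4leaf_catalog(c("a", "b", "c", "d"))
  tri <- cat4$network[cat4$tag == "TRIANGLE"]
  for (con in c("K2P", "K3P")) {
    v <- vapply(tri, function(net) {
      vanishes_on(g1, net, con)$vanishes
    }, TRUE)
    # one skeleton = three labeled reticulation placements
    expect_equal(sum(v), 3L)
    sigs <- vapply(tri[v], seminet:::skeleton_signature, "")
    expect_equal(length(unique(sigs)), 1L)
  }
})

test_that("variety membership is a skeleton property for triangles and double triangles", {
  # vanishing of any invariant is constant across reticulation
  # placements on a fixed labelled skeleton
  g <- builtin_invariants()
  cat4 <- enumerate_4leaf_catalog(c("a", "b", "c", "d"))
  soft <- cat4[cat4$tag %in% c("TRIANGLE", "DOUBLE_TRIANGLE"), ]
  sigs <- vapply(soft$network, seminet:::skeleton_signature, "")
  for (gi in g[c("g1", "g3")]) {
    for (con in c("JC", "K3P")) {
      v <- vapply(soft$network, function(net) vanishes_on(gi, net, con)$vanishes, TRUE)
      for (s in unique(sigs)) {
        expect_equal(length(unique(v[sigs == s])), 1L)
      }
    }
  }
})

test_that("non-vanishing witnesses certify evaluation at an explicit point", {
  g2 <- builtin_invariants()$g2
  fc <- cycle_network(list("a", "b", "c", "d"), ret_block = 1L)
  rep <- vanishes_on(g2, fc, "K3P", method = "modular")
  expect_false(rep$vanishes)
  # re-derive the witness from its seed
  fp <- sample_fourier_parameters(fc, "K3P", seed = rep$witness_seed,
                                  mode = "modular")
  qv <- setNames(seminet:::q_vector(fc, fp, modular = TRUE),
                 seminet:::pattern_strings(4L))
  expect_equal(seminet:::evaluate_qpoly_mod(g2, qv), rep$witness_value)
})
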