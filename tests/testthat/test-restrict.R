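test_that("restriction handles identity, cherries and cycle shortening", {
  net <- fig4a_net()
  expect_true(network_identical(restriction(net, taxa(net)), net))

  # removing all but one block of a cycle collapses the cycle to a tree
  sub <- restriction(net, c("x", "d"))
  expect_equal(validate_network(sub)$r, 0L)

  # keeping 4 blocks incl. the below-reticulation one gives a 4-cycle
  sub2 <- restriction(net, c("x", "a1", "a2", "a3"))
  rep2 <- validate_network(sub2)
  expect_equal(rep2$r, 1L)
  expect_equal(length(network_cycles(sub2)[[1L]]), 4L)
  part <- cycle_partition(sub2, 1L)
  expect_equal(part$block[[which(part$below_reticulation)]], "x")

  # a 4-cycle restricted to 3 blocks becomes a triangle (kept, flagged)
  fc <- cycle_network(list("a", "b", "c", "d"), ret_block = 1L)
  tri <- restriction(fc, c("a", "b", "c"))
  expect_false(validate_network(tri)$triangle_free)
  expect_equal(validate_network(tri)$r, 1L)

  expect_error(restriction(net, c("x")), "at least 2")
  expect_error(restriction(net, c("x", "zz")), "subset")
})

test_that("restriction is idempotent over nested subsets", {
  for (s in 1:8) {
    net <- random_network(8, 2, seed = 200 + s)
    tx <- taxa(net)
    A <- tx[1:6]
    B <- tx[c(1, 3, 5, 6)]
    expect_true(network_identical(restriction(restriction(net, A), B),
                                  restriction(net, B)))
  }
})

test_that("restriction does not depend on the rooting used", {
  for (s in 1:5) {
    net <- random_network(7, 2, seed = 300 + s)
    tx <- taxa(net)
    A <- tx[c(1, 2, 4, 6)]
    base <- restriction(net, A)
    for (e in head(seminet:::valid_root_edges(net), 4L)) {
      rn <- root_network(net, at_edge = e)
      alt <- to_semidirected(rn)
      expect_true(network_identical(restriction(alt, A), base))
    }
  }
})

test_that("quotients are additive in r and independent of the representative", {
  for (s in 1:200) {
    n <- 6L + (s %% 3L)
    net <- random_network(n, 1L + (s %% 2L), seed = 400 + s)
    sp <- splits(net)
    sp <- sp[!sp$trivial, ]
    if (nrow(sp) == 0L) next
    for (i in seq_len(min(nrow(sp), if (s <= 20L) 2L else 1L))) {
      X <- sp$side_a[[i]]
      Y <- sp$side_b[[i]]
      qX <- quotient(net, X)
      qY <- quotient(net, Y)
      expect_equal(validate_network(qX)$r + validate_network(qY)$r,
                   validate_network(net)$r)
      # representative independence: any x in X gives the same skeleton
      if (length(X) >= 2L && s <= 20L) {
        alt <- restriction(net, c(X[[2L]], Y))
        perm <- setNames(c(X[[1L]], Y), c(X[[2L]], Y))
        expect_true(seminet:::skeleton_identical(relabel_network(alt, perm), qX))
      }
    }
  }
  expect_error(quotient(fig4a_net(), c("a1", "a2")), "not one side")
})

test_that("distinct networks with a common split have a distinct quotient pair", {
  # Observation-1-style property
  found <- 0L
  for (s in 1:40) {
    n1 <- random_network(7, 1, seed = 500 + s)
    n2 <- random_network(7, 1, seed = 800 + s)
    if (network_identical(n1, n2)) next
    com <- common_splits(n1, n2)
    com <- com[!com$trivial, ]
    if (nrow(com) == 0L) next
    found <- found + 1L
    X <- com$side_a[[1L]]
    Y <- com$side_b[[1L]]
    expect_true(!network_identical(quotient(n1, X), quotient(n2, X)) ||
                  !network_identical(quotient(n1, Y), quotient(n2, Y)))
  }
  expect_gt(found, 0L)
})
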