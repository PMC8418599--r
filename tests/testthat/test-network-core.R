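test_that("unrooting gives structurally valid semi-directed networks", {
  sd_tree <- to_semidirected(parse_enewick("((a,b),(c,d));"))
  expect_equal(sd_tree$nv, 6L)
  rep <- validate_network(sd_tree)
  expect_equal(rep$level, 0L)
  expect_true(rep$triangle_free)
  expect_equal(rep$r, 0L)

  # a root whose child is a reticulation leaves parallel reticulation
  # edges after unrooting; they must be identified and r drops to 0
  rn <- parse_enewick("((a)#H1,(#H1,(b,c)));")
  sd <- to_semidirected(rn)
  expect_equal(validate_network(sd)$r, 0L)
  expect_true(network_identical(sd, to_semidirected(parse_enewick("(a,(b,c));"))))
})

test_that("validate reports shape, level and triangle-freeness", {
  four_cycle <- cycle_network(list("a", "b", "c", "d"), ret_block = 1L)
  rep <- validate_network(four_cycle)
  expect_equal(rep$level, 1L)
  expect_true(rep$triangle_free)
  expect_equal(rep$r, 1L)

  tri <- cycle_network(list(c("a", "b"), "c", "d"), ret_block = 1L)
  rep2 <- validate_network(tri)
  expect_equal(rep2$level, 1L)
  expect_false(rep2$triangle_free)
  expect_equal(rep2$r, 1L)
})

test_that("rooted vertex-count identity holds on random networks", {
  for (s in 1:25) {
    n <- 4L + (s %% 5L)
    r <- s %% 3L
    if (2L * r > n - 2L) r <- 0L
    net <- random_network(n, r, seed = s)
    rn <- root_network(net)
    expect_equal(n_reticulations(rn), r)
    # the rooted representative subdivides one edge of the (already
    # suppressed) semi-directed graph, so compare after re-unrooting
    expect_equal(parse_enewick(write_enewick(rn))$nv, 2L * n + 2L * r - 1L)
  }
})

test_that("rooting is reversible and root placement does not matter", {
  for (s in 1:10) {
    net <- random_network(7, 2, seed = 100 + s)
    expect_true(network_identical(to_semidirected(root_network(net)), net))
    cand <- seminet:::valid_root_edges(net)
    for (e in head(cand, 3L)) {
      expect_true(network_identical(to_semidirected(root_network(net, at_edge = e)), net))
    }
  }
})

test_that("network equality is leaf-labelled isomorphism, not identity of encoding", {
  a <- quartet_tree("a", "b", "c", "d")
  b <- to_semidirected(parse_enewick("((c,d),(b,a));"))
  expect_true(network_identical(a, b))
  expect_false(network_identical(a, quartet_tree("a", "c", "b", "d")))
  perm <- setNames(c("b", "a", "d", "c"), c("a", "b", "c", "d"))
  expect_true(network_identical(relabel_network(a, perm), a))
})

test_that("random networks satisfy the requested constraints and are reproducible", {
  net <- random_network(8, 3, seed = 7)
  rep <- validate_network(net)
  expect_equal(rep$r, 3L)
  expect_equal(rep$level, 1L)
  expect_true(rep$triangle_free)
  expect_true(rep$rootable)
  expect_true(network_identical(net, random_network(8, 3, seed = 7)))
  expect_error(random_network(4, 2, seed = 1), "infeasible")
  with_triangles <- random_network(5, 2, seed = 3, triangle_free = FALSE)
  expect_equal(validate_network(with_triangles)$r, 2L)
})
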