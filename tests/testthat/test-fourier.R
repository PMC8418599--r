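test_that("the Hadamard transform is inverted exactly and maps uniform to a point mass", {
  set.seed(4)
  p <- runif(4^3)
  p <- p / sum(p)
  round_trip <- inverse_fourier(fourier_transform(p))
  expect_equal(round_trip$probability, p, tolerance = 1e-14)

  unif <- rep(1 / 4^4, 4^4)
  q <- fourier_transform(unif)
  expect_equal(q$q[q$pattern == "AAAA"], 1)
  expect_true(all(abs(q$q[q$pattern != "AAAA"]) < 1e-15))

  expect_error(fourier_transform(runif(10)), "power of 4")
})

test_that("q vanishes exactly off the zero group-sum set for trees and networks", {
  nets <- list(
    to_semidirected(parse_enewick("((a,b),(c,d));")),
    to_semidirected(parse_enewick("(((a,(b)#H1),(#H1,c)),d);")),
    random_network(5, 2, seed = 17, triangle_free = FALSE)
  )
  for (net in nets) {
    for (con in c("JC", "K2P", "K3P")) {
      params <- sample_parameters(net, con, seed = 21)
      q <- fourier_transform(site_pattern_distribution(net, params))
      off <- vapply(q$pattern, group_sum, 1L) != 0L
      expect_true(all(abs(q$q[off]) < 1e-13))
      # and identically zero in the direct parameterization
      q2 <- fourier_parameterization(net, as_fourier_params(params))
      expect_true(all(q2$q[off] == 0))
    }
  }
})

test_that("transform of the marginalised distribution equals the monomial parameterization", {
  # spot check here; the full catalog sweep is an acceptance test
  net <- cycle_network(list("a", "b", "c", "d"), ret_block = 2L)
  for (con in c("JC", "K2P", "K3P")) {
    for (s in 1:5) {
      params <- random_exact_params(net, con, seed = 31 + s)
      q1 <- fourier_transform(site_pattern_distribution(net, params))$q
      q2 <- fourier_parameterization(net, as_fourier_params(params))$q
      expect_identical(q1, q2)
    }
  }
})

test_that("the monomial side index can use either side of an edge split", {
  # on the zero group-sum set the sums over the two sides of any split
  # coincide, so the parameter index does not depend on the chosen side
  for (net in list(quartet_tree("a", "b", "c", "d"),
                   cycle_network(list("a", "b", "c", "d"), ret_block = 1L),
                   random_network(6, 1, seed = 55))) {
    n <- length(taxa(net))
    codes <- seminet:::pattern_codes(n)
    on_support <- seminet:::xor_reduce(codes, seq_len(n)) == 0L
    dt <- displayed_trees(net, tibble::tibble(
      ret = as.integer(names(net$ret_pairs)),
      delta = rep(0.5, length(net$ret_pairs))
    ))
    for (i in seq_len(nrow(dt))) {
      sides <- seminet:::edge_sides(net, dt$kept[[i]])
      for (side in sides) {
        s1 <- seminet:::xor_reduce(codes, side)
        s2 <- seminet:::xor_reduce(codes, setdiff(seq_len(n), side))
        expect_true(all(s1[on_support] == s2[on_support]))
      }
    }
  }
})

test_that("distributions are invariant under root relocation", {
  for (s in 1:6) {
    net <- random_network(6, 2, seed = 700 + s)
    params <- random_exact_params(net, "K3P", seed = s)
    cand <- seminet:::valid_root_edges(net)
    base <- spd_prob(net, params)
    for (e in head(cand, 3L)) {
      rooted <- root_network(net, at_edge = e)
      expect_identical(seminet:::spd_vector(rooted, params), base)
    }
  }
})
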