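test_that("displayed trees have the right count and weights", {
  tr <- to_semidirected(parse_enewick("((a,b),(c,d));"))
  dt0 <- displayed_trees(tr)
  expect_equal(nrow(dt0), 1L)
  expect_equal(dt0$weight, 1)

  net <- to_semidirected(parse_enewick("(((a,(b)#H1),(#H1,c)),d);"))
  w <- tibble::tibble(ret = as.integer(names(net$ret_pairs)), delta = 0.3)
  dt1 <- displayed_trees(net, w)
  expect_equal(nrow(dt1), 2L)
  expect_setequal(dt1$weight, c(0.3, 0.7))
  # sigma_i = 0 deletes e0 and keeps e1, which carries probability delta
  expect_equal(dt1$weight[vapply(dt1$sigma, function(s) s[[1L]] == 0L, TRUE)], 0.3)

  net2 <- parse_enewick("(((a,(b)#H1),(#H1,c)),((d)#H2,(#H2,e)));")
  p2 <- sample_parameters(net2, "JC", seed = 1)
  dt2 <- displayed_trees(net2, p2$weights)
  expect_equal(nrow(dt2), 4L)
  expect_equal(sum(dt2$weight), 1)
})

test_that("identity transition matrices copy the root state to every leaf", {
  net <- to_semidirected(parse_enewick("((a,b),(c,d));"))
  params <- sample_parameters(net, "K3P", seed = 1)
  params$edges$alpha <- 1
  params$edges$beta <- params$edges$gamma <- params$edges$delta <- 0
  p <- site_pattern_distribution(net, params)
  const <- p$pattern %in% c("AAAA", "GGGG", "CCCC", "TTTT")
  expect_equal(p$probability[const], rep(0.25, 4L))
  expect_true(all(p$probability[!const] == 0))
})

test_that("the pruning DP agrees with explicit marginalisation over assignments", {
  # small enough to sum over every internal-state assignment directly
  rn <- parse_enewick("((a,b),c);")
  for (con in c("JC", "K2P", "K3P")) {
    params <- random_exact_params(rn, con, seed = 11)
    expect_identical(spd_prob(rn, params), brute_force_spd(rn, params))
  }
  # 2-leaf JC model: exact dyadic arithmetic, equal same-base masses
  rn2 <- parse_enewick("(a,b);")
  params <- random_exact_params(rn2, "JC", seed = 5)
  p <- spd_prob(rn2, params)
  expect_identical(p, brute_force_spd(rn2, params))
  expect_equal(unname(p[c(6, 11, 16)]), rep(p[[1L]], 3L))  # p_GG = p_CC = p_TT = p_AA
})

test_that("site-pattern distributions are proper probability distributions", {
  for (s in 1:6) {
    net <- random_network(5 + (s %% 3), s %% 3, seed = 1400 + s)
    params <- sample_parameters(net, c("JC", "K2P", "K3P")[(s %% 3) + 1], seed = s)
    p <- spd_prob(net, params)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("a network distribution is the weighted sum of its displayed-tree distributions", {
  net <- to_semidirected(parse_enewick("(((a,(b)#H1),(#H1,c)),d);"))
  params <- sample_parameters(net, "K2P", seed = 8)
  rn <- root_network(net)
  mats <- seminet:::rooted_edge_matrices(rn, params)
  dt <- displayed_trees(rn, params$weights)
  manual <- Reduce(`+`, lapply(seq_len(nrow(dt)), function(i) {
    dt$weight[[i]] * seminet:::tree_joint_distribution(rn, dt$kept[[i]], mats)
  }))
  expect_equal(spd_prob(net, params), manual)
})

test_that("degree-2 suppression composes matrices without leaving the constraint class", {
  for (con in c("JC", "K2P", "K3P")) {
    p <- sample_parameters(parse_enewick("(a,b);"), con, seed = 3)
    M1 <- transition_matrix(p$edges$alpha[[1]], p$edges$beta[[1]],
                            p$edges$gamma[[1]], p$edges$delta[[1]])
    M2 <- transition_matrix(p$edges$alpha[[2]], p$edges$beta[[2]],
                            p$edges$gamma[[2]], p$edges$delta[[2]])
    M <- M1 %*% M2
    # composite is again a K3P-template matrix with the same equalities
    expect_equal(M, transition_matrix(M[1, 1], M[1, 2], M[1, 3], M[1, 4]))
    if (con == "JC") expect_equal(M[1, 2], M[1, 3])
    if (con %in% c("JC", "K2P")) expect_equal(M[1, 2], M[1, 4])
    expect_equal(unname(rowSums(M)), rep(1, 4))
  }
})

test_that("parallel reticulation edges reduce to a convex matrix sum", {
  # two-leaf network whose reticulation sits under the root: both
  # reticulation edges connect the same pair after unrooting, so the
  # model must equal a single edge carrying delta*M + (1-delta)*M'
  rn <- parse_enewick("((a)#H1,(#H1,b));")
  params <- sample_parameters(rn, "K3P", seed = 13)
  ret <- as.integer(names(rn$ret_pairs)[[1L]])
  pair <- rn$ret_pairs[[1L]]
  # neutral stem between the root and the non-reticulation child, so the
  # two reticulation edges are the parallel pair up to that identity
  Y <- setdiff(rn$edges[rn$edges[, 1L] == rn$root, 2L], ret)
  stem <- which(rn$edges[, 1L] == rn$root & rn$edges[, 2L] == Y)
  params$edges[stem, c("alpha", "beta", "gamma", "delta")] <- list(1, 0, 0, 0)
  p_net <- spd_prob(rn, params)
  mats <- seminet:::rooted_edge_matrices(rn, params)
  delta <- params$weights$delta[[1L]]
  Mmix <- delta * mats[[pair[["e1"]]]] + (1 - delta) * mats[[pair[["e0"]]]]
  leaf_a <- which(rn$labels == "a")
  leaf_b <- which(rn$labels == "b")
  Ma <- mats[[which(rn$edges[, 2L] == leaf_a)]]
  Mb <- mats[[which(rn$edges[, 2L] == leaf_b)]]
  manual <- numeric(16L)
  for (i in 0:3) {
    for (j in 0:3) {
      pr <- 0
      for (k in 0:3) pr <- pr + 0.25 * (Mmix %*% Ma)[k + 1, i + 1] * Mb[k + 1, j + 1]
      manual[i * 4 + j + 1] <- pr
    }
  }
  expect_equal(p_net, manual)
})

test_that("alignments are reproducible draws from the model distribution", {
  net <- to_semidirected(parse_enewick("((a,b),(c,d));"))
  params <- sample_parameters(net, "JC", seed = 2)
  expect_error(simulate_alignment(net, params, length = 0, seed = 1), ">= 1")
  a1 <- simulate_alignment(net, params, length = 200, seed = 9)
  a2 <- simulate_alignment(net, params, length = 200, seed = 9)
  expect_identical(a1, a2)
  expect_equal(nchar(a1$sequence), rep(200L, 4L))

  # empirical frequencies within 4 standard errors of the model
  p <- site_pattern_distribution(net, params)
  big <- simulate_alignment(net, params, length = 40000, seed = 10)
  mat <- do.call(rbind, strsplit(big$sequence, ""))
  pats <- apply(mat, 2L, paste0, collapse = "")
  freq <- table(factor(pats, levels = p$pattern)) / length(pats)
  se <- sqrt(p$probability * (1 - p$probability) / length(pats))
  expect_true(all(abs(as.numeric(freq) - p$probability) <= 4 * se + 1e-12))

  # identity matrices give constant columns
  params$edges$alpha <- 1
  params$edges$beta <- params$edges$gamma <- params$edges$delta <- 0
  aln <- simulate_alignment(net, params, length = 50, seed = 3)
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  expect_true(all(apply(m, 2L, function(col) length(unique(col)) == 1L)))
})
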