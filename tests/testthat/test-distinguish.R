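test_that("4-leaf pair verdicts follow the verdict grid semantics", {
  t1 <- quartet_tree("a", "b", "c", "d")
  t2 <- quartet_tree("a", "c", "b", "d")
  expect_equal(pair_verdict(t1, t2, "JC")$outcome, "DISTINGUISHABLE")

  fc <- cycle_network(list("a", "b", "c", "d"), ret_block = 1L)
  v <- pair_verdict(fc, t1, "K2P")
  expect_equal(v$outcome, "LEFT_NOT_SUBSET")
  expect_gt(length(v$witnesses_12), 0L)

  # triangle versus double triangle: only the double-triangle variety
  # escapes containment
  tri <- cycle_network(list(c("a", "b"), "c", "d"), ret_block = 1L)
  dt <- seminet:::double_triangle_network(c("a", "b"), c("c", "d"), "a", "c")
  expect_equal(pair_verdict(tri, dt, "K3P")$outcome, "RIGHT_NOT_SUBSET")

  dt2 <- seminet:::double_triangle_network(c("a", "b"), c("c", "d"), "b", "d")
  expect_true(seminet:::skeleton_identical(dt, dt2))
  expect_equal(pair_verdict(dt, dt2, "JC")$outcome, "SKELETON_CONDITIONAL")

  expect_error(pair_verdict(t1, t1, "JC"), "distinct")
  td <- tidy(pair_verdict(fc, t1, "K2P"))
  expect_equal(td$witnessed, c(TRUE, FALSE))
})

test_that("4-cycle versus tree yields a full-leaf-set witness", {
  fc <- cycle_network(list("a", "b", "c", "d"), ret_block = 1L)
  tr <- quartet_tree("a", "b", "c", "d")
  cert <- find_noncontainment_certificate(fc, tr, "JC")
  expect_equal(cert$kind, "FOUR_LEAF_WITNESS")
  expect_equal(cert$subset, c("a", "b", "c", "d"))
  expect_true(verify_certificate(cert))
  expect_error(find_noncontainment_certificate(tr, fc, "JC"), "swap")
  expect_error(find_noncontainment_certificate(fc, fc, "JC"), "distinct")
})

test_that("networks glued on a common cherry recurse through the split", {
  # same cherry {g,h}; behind it, a 4-cycle whose {c,d} block is split
  # into two singleton blocks of a 5-cycle in the second network. All
  # induced 4-cycles agree, the cherry is the only common non-trivial
  # split, and the quotients stay distinct, forcing a split recursion.
  na <- to_semidirected(parse_enewick("((g,h),(((c,d),(e,(f)#H1)),#H1));"))
  nb <- to_semidirected(parse_enewick("((g,h),((c,(d,(e,(f)#H1))),#H1));"))
  expect_false(network_identical(na, nb))
  expect_true(all(validate_network(na)$triangle_free,
                  validate_network(nb)$triangle_free))
  cert <- find_noncontainment_certificate(na, nb, "K2P")
  expect_true(verify_certificate(cert))
  td <- tidy(cert)
  expect_equal(td$kind[[1L]], "SPLIT_RECURSION")
  expect_true(all(diff(td$n_taxa) < 0))
  # the opposite direction catches the extra 4-cycle directly
  cert2 <- find_noncontainment_certificate(nb, na, "K2P")
  expect_true(verify_certificate(cert2))
  expect_equal(cert2$kind, "FOUR_LEAF_WITNESS")
})

test_that("distinguishability returns two independently verifiable certificates", {
  n1 <- random_network(8, 2, seed = 1201)
  n2 <- random_network(8, 2, seed = 1202)
  expect_false(network_identical(n1, n2))
  d <- distinguishable(n1, n2, "JC")
  expect_equal(d$verdict, "DISTINGUISHABLE")
  expect_true(verify_certificate(d$cert_12))
  expect_true(verify_certificate(d$cert_21))
  # swapping arguments swaps the certificate directions
  d2 <- distinguishable(n2, n1, "JC")
  expect_equal(tidy(d2$cert_12)$kind, tidy(d$cert_21)$kind)
  g <- glance(d)
  expect_equal(g$verdict, "DISTINGUISHABLE")
  expect_equal(g$r, 2L)
})

test_that("unequal reticulation counts are rejected by the two-sided decision", {
  n1 <- random_network(7, 2, seed = 1301)
  n2 <- random_network(7, 1, seed = 1302)
  expect_error(distinguishable(n1, n2, "JC"), "differ")
  cert <- find_noncontainment_certificate(n1, n2, "JC")
  expect_true(verify_certificate(cert))
})

test_that("split case analysis recognises its three branches", {
  t_ab <- quartet_tree("a", "b", "c", "d")
  expect_equal(split_case_analysis(t_ab, quartet_tree("a", "b", "c", "d"))$case,
               "COMMON_SPLIT")
  expect_equal(split_case_analysis(t_ab, quartet_tree("a", "c", "b", "d"))$case,
               "CONFLICTING")
  ncyc <- cycle_network(list("a", "b", "c", "d", "e"), ret_block = 1L)
  other <- random_network(5, 1, seed = 77, labels = c("a", "b", "c", "d", "e"))
  expect_equal(split_case_analysis(other, ncyc)$case,
               if (!is.null(conflicting_splits(other, ncyc))) "CONFLICTING"
               else "NO_NONTRIVIAL_SPLIT_IN_N2")
})
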