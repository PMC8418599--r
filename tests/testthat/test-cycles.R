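test_that("cycle partitions reproduce the published 9-taxon examples", {
  n1 <- fig3_n1()
  n2 <- fig3_n2()
  p1 <- cycle_partition(n1, 1L)
  expect_setequal(
    vapply(p1$block, paste, "", collapse = ","),
    c("a,a1,a4", "a2,b", "a3", "c", "d,x")
  )
  expect_equal(p1$block[[which(p1$below_reticulation)]], c("d", "x"))

  p2 <- cycle_partition(n2, 1L)
  expect_setequal(
    vapply(p2$block, paste, "", collapse = ","),
    c("a,a1", "a4", "a2", "b", "a3", "c", "d,x")
  )
  expect_equal(p2$block[[which(p2$below_reticulation)]], c("d", "x"))

  # the 7-block partition refines the 5-block one, not conversely
  expect_true(refines(n2, 1L, n1, 1L))
  expect_false(refines(n1, 1L, n2, 1L))
  expect_true(refines(n1, 1L, n1, 1L))
})

test_that("4-cycle networks induce singleton blocks", {
  fc <- cycle_network(list("p", "q", "r", "s"), ret_block = 3L)
  part <- cycle_partition(fc, 1L)
  expect_equal(sort(unlist(part$block)), c("p", "q", "r", "s"))
  expect_true(all(lengths(part$block) == 1L))
  expect_equal(part$block[[which(part$below_reticulation)]], "r")
})

test_that("meeting at a cycle and inducing a cycle differ as described", {
  net <- fig4a_net()
  # three leaves from distinct blocks meet but do not induce
  expect_false(is.null(meets_at_cycle(net, c("a1", "a2", "a3"))))
  expect_false(induces_cycle(net, c("a1", "a2", "a3")))
  # adding a below-reticulation leaf makes the restriction a 4-cycle
  expect_false(is.null(meets_at_cycle(net, c("x", "a1", "a2", "a3"))))
  expect_true(induces_cycle(net, c("x", "a1", "a2", "a3")))
  # two leaves in the same block never meet
  expect_null(meets_at_cycle(net, c("x", "d", "a1")))
  expect_error(meets_at_cycle(net, c("a1", "a2")), "at least 3")
})

test_that("4-subsets inducing 4-cycles through three common leaves meet at one cycle", {
  # property behind the refinement argument
  checked <- 0L
  for (s in 1:12) {
    net <- random_network(8, 2, seed = 600 + s)
    tx <- taxa(net)
    quads <- utils::combn(tx, 4L, simplify = FALSE)
    inducing <- Filter(function(A) induces_cycle(net, A), quads)
    if (length(inducing) < 2L) next
    for (i in seq_along(inducing)) {
      for (j in seq_len(i - 1L)) {
        if (length(intersect(inducing[[i]], inducing[[j]])) != 3L) next
        c1 <- meets_at_cycle(net, inducing[[i]])
        c2 <- meets_at_cycle(net, inducing[[j]])
        expect_setequal(c1, c2)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 0L)
})

test_that("refinement_check follows the constructive argument", {
  rc <- refinement_check(fig3_n1(), fig3_n2())
  expect_true(rc$refined)
  expect_true(rc$hypothesis_ok)
  net <- random_network(8, 2, seed = 42)
  self <- refinement_check(net, net, check_hypothesis = FALSE)
  expect_true(self$refined)
})
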