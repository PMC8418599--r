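# Fixture networks reproduced from their published descriptions: the two
# 9-taxon networks whose cycles illustrate partition refinement, and the
# network used for the meet-versus-induce distinction. Pendant subtree
# shapes within blocks are immaterial to every property tested.

fig3_n1 <- function() {
  cycle_network(
    list(c("a", "a1", "a4"), c("a2", "b"), "a3", "c", c("x", "d")),
    ret_block = 5L
  )
}

fig3_n2 <- function() {
  cycle_network(
    list(c("a", "a1"), "a4", "a2", "b", "a3", "c", c("x", "d")),
    ret_block = 7L
  )
}

fig4a_net <- function() {
  cycle_network(
    list("a1", "a", "a2", "b", "a3", "c", c("x", "d")),
    ret_block = 7L
  )
}

# group codes of a pattern string under A=(0,0), G=(1,0), C=(0,1), T=(1,1)
pat_codes <- function(pattern) {
  match(strsplit(pattern, "")[[1L]], c("A", "G", "C", "T")) - 1L
}

group_sum <- function(pattern) Reduce(bitwXor, pat_codes(pattern))

# independent brute-force implementation of the site-pattern probability:
# explicit sum over all assignments of states to every vertex, for each
# displayed tree; tractable only for very small networks
brute_force_spd <- function(rn, params) {
  mats <- seminet:::rooted_edge_matrices(rn, params)
  dt <- displayed_trees(rn, params$weights)
  tx <- sort(rn$labels[!is.na(rn$labels)])
  n <- length(tx)
  nv <- rn$nv
  leafv <- match(tx, rn$labels)
  p <- numeric(4L^n)
  states <- seminet:::pattern_codes(nv)
  for (i in seq_len(nrow(dt))) {
    kept <- dt$kept[[i]]
    for (a in seq_len(4L^nv)) {
      phi <- states[a, ]
      pr <- 0.25
      for (row in kept) {
        pr <- pr * mats[[row]][phi[rn$edges[row, 1L]] + 1L,
                               phi[rn$edges[row, 2L]] + 1L]
      }
      idx <- 1L + sum(phi[leafv] * 4L^((n - 1L):0L))
      p[idx] <- p[idx] + dt$weight[[i]] * pr
    }
  }
  p
}

# independent q-polynomial evaluator: nested loops, no shared code with
# evaluate_qpoly beyond the variable naming
eval_qpoly_by_hand <- function(poly, q_tbl) {
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(q_tbl))) lookup[[q_tbl$pattern[[i]]]] <- q_tbl$q[[i]]
  total <- 0
  for (t in poly$terms) {
    acc <- t$coef
    for (v in t$vars) acc <- acc * lookup[[v]]
    total <- total + acc
  }
  total
}

random_exact_params <- function(net, constraint, seed) {
  sample_parameters(net, constraint, seed, exact = TRUE)
}

spd_prob <- function(net, params) site_pattern_distribution(net, params)$probability
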