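#' Cycles of a level-1 semi-directed network
#'
#' The skeleton cycles are exactly the biconnected components with at
#' least three vertices. Each is returned as an ordered vertex sequence.
#'
#' @param net a [semidirected_network()].
#' @return A list of integer vertex sequences.
#' @export
network_cycles <- function(net) sd_cycles(net)

#' Partition of the taxa induced by a cycle
#'
#' Each cut-edge incident to a cycle separates one block of taxa from the
#' cycle; together the blocks partition the taxon set. The block attached
#' at the reticulation vertex is *below the reticulation*. Blocks are
#' listed in cycle order starting at the reticulation vertex, in the
#' direction whose first block has the smaller minimum taxon.
#'
#' @param net a level-1 [semidirected_network()].
#' @param cycle an integer vertex sequence as returned by
#'   [network_cycles()], or the index of a cycle.
#' @return A tibble with list-column `block` (sorted taxa), logical
#'   `below_reticulation` and the `cycle_vertex` each block hangs from.
#'   The ordered cycle is attached as attribute `"cycle"`.
#' @export
cycle_partition <- function(net, cycle) {
  cyc <- sd_cycles(net)
  if (length(cycle) == 1L && is.numeric(cycle) && cycle <= length(cyc)) {
    cycle <- cyc[[cycle]]
  } else {
    hit <- which(map_lgl(cyc, setequal, cycle))
    if (length(hit) != 1L) abort("not a cycle of this network")
    cycle <- cyc[[hit]]
  }
  rets <- intersect(ret_vertices(net), cycle)
  if (length(rets) != 1L) abort("cycle must contain exactly one reticulation (level-1)")
  k <- length(cycle)
  # rotate so the reticulation comes first
  i <- which(cycle == rets)
  seqv <- cycle[((seq_len(k) + i - 2L) %% k) + 1L]
  blocks_for <- function(vs) {
    map(vs, function(v) {
      inc <- which(net$edges[, 1L] == v | net$edges[, 2L] == v)
      pend <- inc[!(net$edges[inc, 1L] %in% cycle & net$edges[inc, 2L] %in% cycle)]
      w <- setdiff(net$edges[pend, ], v)
      comp <- component_after_removal(net, pend, w)
      sort(net$labels[intersect(comp, which(!is.na(net$labels)))])
    })
  }
  fwd <- seqv
  rev_ <- c(seqv[[1L]], rev(seqv[-1L]))
  bf <- blocks_for(fwd)
  br <- blocks_for(rev_)
  use_fwd <- length(bf) <= 2L || bf[[2L]][[1L]] <= br[[2L]][[1L]]
  vs <- if (use_fwd) fwd else rev_
  blocks <- if (use_fwd) bf else br
  out <- tibble(
    block = blocks,
    below_reticulation = seq_along(vs) == 1L,
    cycle_vertex = vs
  )
  attr(out, "cycle") <- cycle
  out
}

#' Do a set of leaves meet at / induce a cycle?
#'
#' Three or more leaves *meet at* a cycle if each lies in a different
#' block of the partition that cycle induces; such a cycle is unique when
#' it exists. They *induce* a cycle if the restriction of the network to
#' them is a t-cycle network. Inducing implies meeting; the converse holds
#' when one of the leaves is below the reticulation.
#'
#' @param net a triangle-free level-1 [semidirected_network()].
#' @param leaves at least three taxon names.
#' @return `meets_at_cycle()`: the ordered vertex sequence of the cycle,
#'   or `NULL`. `induces_cycle()`: `TRUE`/`FALSE`.
#' @export
meets_at_cycle <- function(net, leaves) {
  if (length(leaves) < 3L) abort("need at least 3 leaves")
  for (cv in sd_cycles(net)) {
    part <- cycle_partition(net, cv)
    idx <- map_int(leaves, function(x) {
      hit <- which(map_lgl(part$block, function(b) x %in% b))
      hit[[1L]]
    })
    if (!anyDuplicated(idx)) return(attr(part, "cycle"))
  }
  NULL
}

#' @rdname meets_at_cycle
#' @export
induces_cycle <- function(net, leaves) {
  if (length(leaves) < 3L) abort("need at least 3 leaves")
  sub <- restriction(net, leaves)
  rep <- validate_network(sub)
  cyc <- sd_cycles(sub)
  rep$r == 1L && length(cyc) == 1L && length(cyc[[1L]]) == length(leaves)
}

#' Cycle refinement
#'
#' Cycle `cycle2` of `net2` refines cycle `cycle1` of `net1` when both
#' have the same below-reticulation block and the remaining blocks of
#' `cycle2` refine (are nested inside) those of `cycle1`.
#'
#' @param net2,net1 triangle-free level-1 networks on the same taxa.
#' @param cycle2,cycle1 cycles of the respective networks (vertex
#'   sequences or indices).
#' @return `TRUE`/`FALSE`.
#' @export
refines <- function(net2, cycle2, net1, cycle1) {
  if (!identical(taxa(net1), taxa(net2))) abort("networks must share a taxon set")
  p2 <- cycle_partition(net2, cycle2)
  p1 <- cycle_partition(net1, cycle1)
  x2 <- p2$block[[which(p2$below_reticulation)]]
  x1 <- p1$block[[which(p1$below_reticulation)]]
  if (!identical(x1, x2)) return(FALSE)
  a_blocks <- p1$block[!p1$below_reticulation]
  b_blocks <- p2$block[!p2$below_reticulation]
  all(map_lgl(b_blocks, function(b) {
    any(map_lgl(a_blocks, function(a) all(b %in% a)))
  }))
}
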