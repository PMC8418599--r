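#' The catalog of 4-leaf level-1 semi-directed networks
#'
#' Enumerates every leaf-labelled 4-leaf level-1 semi-directed network on
#' the given taxa: the 3 quartet trees, the single-triangle networks, the
#' 4-cycle networks and the double-triangle networks (the only r = 2
#' shape that fits on four leaves). Candidates that admit no valid rooting
#' are excluded. Networks are tagged by shape and grouped into classes
#' under the leaf-relabeling action; grouping is computed by isomorphism
#' search, not assumed.
#'
#' @param labels four taxon names.
#' @return A tibble with columns `network` (list of
#'   [semidirected_network()]), `tag` (one of `"Q"`, `"TRIANGLE"`,
#'   `"DOUBLE_TRIANGLE"`, `"FOUR_CYCLE"`), and `class_id` (relabeling
#'   class, 1-based in order of first appearance).
#' @examples
#' cat4 <- enumerate_4leaf_catalog(c("a", "b", "c", "d"))
#' table(cat4$tag)
#' max(cat4$class_id) # 6 classes up to relabeling
#' @export
enumerate_4leaf_catalog <- function(labels) {
  stopifnot(length(labels) == 4L, !anyDuplicated(labels))
  labels <- sort(labels)
  key <- paste(labels, collapse = ",")
  if (!is.null(the$catalog[[key]])) return(the$catalog[[key]])

  nets <- list(); tags <- character()
  push <- function(net, tag) {
    nets[[length(nets) + 1L]] <<- net
    tags[[length(tags) + 1L]] <<- tag
  }
  splits3 <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  for (s in splits3) {
    pq <- labels[s]; rs <- setdiff(labels, pq)
    push(quartet_tree(pq[1L], pq[2L], rs[1L], rs[2L]), "Q")
  }
  for (ch in combn(4L, 2L, simplify = FALSE)) {
    pq <- labels[ch]; rs <- setdiff(labels, pq)
    for (rb in 1:3) {
      push(cycle_network(list(pq, rs[1L], rs[2L]), ret_block = rb), "TRIANGLE")
    }
  }
  others <- setdiff(labels, labels[1L])
  # a necklace on 4 beads with the first taxon fixed is determined by the
  # taxon opposite it: put each of the other three in the middle slot
  arr3 <- list(others[c(2L, 1L, 3L)], others, others[c(1L, 3L, 2L)])
  for (o in arr3) {
    blocks <- as.list(c(labels[1L], o))
    for (rb in 1:4) push(cycle_network(blocks, ret_block = rb), "FOUR_CYCLE")
  }
  for (s in splits3) {
    pq <- labels[s]; rs <- setdiff(labels, pq)
    for (r1 in c("bridge", pq)) {
      for (r2 in c("bridge", rs)) {
        cand <- double_triangle_network(pq, rs, r1, r2)
        if (validate_network(cand)$rootable) push(cand, "DOUBLE_TRIANGLE")
      }
    }
  }
  stopifnot(all(map_lgl(nets, function(n) {
    v <- validate_network(n)
    v$rootable && v$level <= 1L && v$is_binary
  })))
  # safety: no duplicates within the enumeration
  for (tg in unique(tags)) {
    idx <- which(tags == tg)
    for (i in seq_along(idx)) {
      for (j in seq_len(i - 1L)) {
        if (network_identical(nets[[idx[i]]], nets[[idx[j]]])) {
          abort("internal error: duplicate catalog entry")
        }
      }
    }
  }
  class_id <- integer(length(nets))
  reps <- list()
  for (i in seq_along(nets)) {
    found <- 0L
    for (k in seq_along(reps)) {
      if (tags[[reps[[k]]]] == tags[[i]] &&
          iso_up_to_relabeling(nets[[i]], nets[[reps[[k]]]])) {
        found <- k
        break
      }
    }
    if (found == 0L) {
      reps[[length(reps) + 1L]] <- i
      found <- length(reps)
    }
    class_id[[i]] <- found
  }
  out <- tibble(network = nets, tag = tags, class_id = class_id)
  the$catalog[[key]] <- out
  out
}

# are two networks isomorphic up to a permutation of leaf labels?
iso_up_to_relabeling <- function(net1, net2) {
  tx <- taxa(net1)
  if (!identical(tx, taxa(net2))) return(FALSE)
  perms <- permutations_of(tx)
  for (p in perms) {
    if (network_identical(relabel_network(net1, setNames(p, tx)), net2)) {
      return(TRUE)
    }
  }
  FALSE
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[[i]], rest)
    }
  }
  out
}

# shape tag of an arbitrary 4-leaf level-1 network
classify4 <- function(net) {
  stopifnot(length(taxa(net)) == 4L)
  r <- length(ret_vertices(net))
  if (r == 0L) return("Q")
  if (r == 2L) return("DOUBLE_TRIANGLE")
  k <- length(sd_cycles(net)[[1L]])
  if (k == 3L) "TRIANGLE" else "FOUR_CYCLE"
}
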