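# Direct constructors for level-1 building blocks (used by the catalog,
# the random generator and tests).

# append a pendant subtree on `taxa` hanging from vertex `anchor`;
# `st` is an environment with fields edges (list of c(a, b)), labels
add_pendant_subtree <- function(st, anchor, taxa) {
  new_vertex <- function(label = NA_character_) {
    st$labels <- c(st$labels, label)
    length(st$labels)
  }
  taxa <- sort(taxa)
  if (length(taxa) == 1L) {
    lf <- new_vertex(taxa)
    st$edges[[length(st$edges) + 1L]] <- c(anchor, lf)
    return(invisible(st))
  }
  # caterpillar: anchor - i1 - i2 - ... with leaves hanging off
  prev <- anchor
  for (j in seq_len(length(taxa) - 1L)) {
    iv <- new_vertex()
    st$edges[[length(st$edges) + 1L]] <- c(prev, iv)
    lf <- new_vertex(taxa[[j]])
    st$edges[[length(st$edges) + 1L]] <- c(iv, lf)
    prev <- iv
  }
  lf <- new_vertex(taxa[[length(taxa)]])
  st$edges[[length(st$edges) + 1L]] <- c(prev, lf)
  invisible(st)
}

#' Build a level-1 network with a single cycle
#'
#' Constructs a k-cycle semi-directed network whose cut-edges carry the
#' given taxon blocks, in cyclic order, with the reticulation vertex at a
#' chosen block.
#'
#' @param blocks list of character vectors (taxon blocks), in cyclic order
#'   around the cycle; length at least 3.
#' @param ret_block index of the block below the reticulation.
#' @return A [semidirected_network()].
#' @examples
#' cycle_network(list("a", "b", "c", "d"), ret_block = 1)
#' @export
cycle_network <- function(blocks, ret_block = 1L) {
  k <- length(blocks)
  stopifnot(k >= 3L, ret_block >= 1L, ret_block <= k)
  st <- new.env(parent = emptyenv())
  st$labels <- rep(NA_character_, k)
  st$edges <- list()
  ring <- vector("list", k)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    ring[[i]] <- c(i, j)
    st$edges[[length(st$edges) + 1L]] <- c(i, j)
  }
  ring_rows <- seq_len(k)
  for (i in seq_len(k)) add_pendant_subtree(st, i, blocks[[i]])
  edges <- do.call(rbind, st$edges)
  directed <- rep(FALSE, nrow(edges))
  into_ret <- ring_rows[vapply(ring, function(e) ret_block %in% e, TRUE)]
  edges[into_ret, ] <- t(apply(edges[into_ret, , drop = FALSE], 1L, function(e) {
    if (e[[2L]] == ret_block) e else rev(e)
  }))
  directed[into_ret] <- TRUE
  semidirected_network(edges, directed, st$labels)
}

# 4-leaf double-triangle network: two triangles joined by a bridge, each
# carrying two pendant leaves; ret1/ret2 in {"bridge", <taxon name>}
double_triangle_network <- function(pair1, pair2, ret1, ret2) {
  st <- new.env(parent = emptyenv())
  st$labels <- rep(NA_character_, 6L)
  st$edges <- list(
    c(1L, 2L), c(2L, 3L), c(3L, 1L),   # triangle 1: vertices 1(bridge),2,3
    c(4L, 5L), c(5L, 6L), c(6L, 4L),   # triangle 2: vertices 4(bridge),5,6
    c(1L, 4L)                          # bridge
  )
  carriers <- c(2L, 3L, 5L, 6L)
  taxa4 <- c(sort(pair1), sort(pair2))
  for (i in seq_len(4L)) add_pendant_subtree(st, carriers[[i]], taxa4[[i]])
  ret_v <- function(ret, bridge_v, tri_taxa, tri_carriers) {
    if (identical(ret, "bridge")) return(bridge_v)
    tri_carriers[[match(ret, tri_taxa)]]
  }
  rv1 <- ret_v(ret1, 1L, sort(pair1), c(2L, 3L))
  rv2 <- ret_v(ret2, 4L, sort(pair2), c(5L, 6L))
  edges <- do.call(rbind, st$edges)
  directed <- rep(FALSE, nrow(edges))
  for (rv in c(rv1, rv2)) {
    tri <- if (rv %in% 1:3) 1:3 else 4:6
    rows <- which(edges[, 1L] %in% tri & edges[, 2L] %in% tri)
    into <- rows[edges[rows, 1L] == rv | edges[rows, 2L] == rv]
    edges[into, ] <- t(apply(edges[into, , drop = FALSE], 1L, function(e) {
      if (e[[2L]] == rv) e else rev(e)
    }))
    directed[into] <- TRUE
  }
  semidirected_network(edges, directed, st$labels)
}

#' Unrooted quartet tree with split \{p,q\} | \{r,s\}
#'
#' @param p,q,r,s taxon names.
#' @return A [semidirected_network()].
#' @export
quartet_tree <- function(p, q, r, s) {
  to_semidirected(parse_enewick(sprintf("((%s,%s),(%s,%s));", p, q, r, s)))
}
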