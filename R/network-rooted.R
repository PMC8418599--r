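#' Rooted binary phylogenetic networks
#'
#' A rooted binary phylogenetic network on a taxon set is a rooted acyclic
#' digraph in which the root has out-degree two and in-degree zero, leaves
#' have in-degree one and out-degree zero, and every other vertex is either
#' a tree vertex (in 1, out 2) or a reticulation vertex (in 2, out 1).
#' Networks are stored as an integer edge list plus a label vector; the two
#' edges directed into reticulation vertex `v` are kept as an ordered pair
#' `(e0, e1)` so that downstream model code knows which edge carries the
#' inheritance probability.
#'
#' @param edges two-column integer matrix of directed edges (parent, child).
#' @param labels character vector with one entry per vertex; `NA` for
#'   internal vertices, the taxon name for leaves.
#' @param root integer id of the root vertex.
#' @param ret_pairs named list mapping each reticulation vertex id to an
#'   ordered pair of edge row indices `c(e0, e1)`; if `NULL` the pair is
#'   taken in edge-list order.
#' @param validate logical; check the class invariants.
#'
#' @return An object of class `rooted_network`.
#' @seealso [parse_enewick()], [to_semidirected()]
#' @export
rooted_network <- function(edges, labels, root, ret_pairs = NULL,
                           validate = TRUE) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  net <- structure(
    list(nv = length(labels), edges = edges, labels = as.character(labels),
         root = as.integer(root), ret_pairs = ret_pairs),
    class = "rooted_network"
  )
  if (is.null(ret_pairs)) {
    net$ret_pairs <- default_ret_pairs(net)
  }
  if (validate) validate_rooted(net)
  net
}

default_ret_pairs <- function(net) {
  indeg <- tabulate(net$edges[, 2L], nbins = net$nv)
  rets <- which(indeg == 2L)
  pairs <- lapply(rets, function(v) {
    idx <- which(net$edges[, 2L] == v)
    c(e0 = idx[1L], e1 = idx[2L])
  })
  names(pairs) <- as.character(rets)
  pairs
}

validate_rooted <- function(net) {
  nv <- net$nv
  e <- net$edges
  if (any(e < 1L) || any(e > nv)) abort("edge endpoints out of range")
  if (anyDuplicated(paste(e[, 1L], e[, 2L]))) {
    abort("invalid network: parallel edges present")
  }
  indeg <- tabulate(e[, 2L], nbins = nv)
  outdeg <- tabulate(e[, 1L], nbins = nv)
  if (indeg[net$root] != 0L || outdeg[net$root] != 2L) {
    abort("invalid network: root must have in-degree 0 and out-degree 2")
  }
  leaves <- which(!is.na(net$labels))
  if (any(indeg[leaves] != 1L) || any(outdeg[leaves] != 0L)) {
    abort("invalid network: leaves must have in-degree 1, out-degree 0")
  }
  if (any(outdeg == 0L & is.na(net$labels) & seq_len(nv) != net$root)) {
    abort("invalid network: unlabeled vertex with out-degree 0")
  }
  labs <- net$labels[leaves]
  if (anyDuplicated(labs)) {
    abort("invalid network: leaf labels are not a bijection (duplicate taxon)")
  }
  other <- setdiff(which(is.na(net$labels)), net$root)
  ok <- (indeg[other] == 1L & outdeg[other] == 2L) |
    (indeg[other] == 2L & outdeg[other] == 1L)
  if (!all(ok)) {
    abort("invalid network: internal vertices must be binary (degrees (1,2) or (2,1))")
  }
  if (is_cyclic_digraph(e, nv)) abort("invalid network: directed cycle present")
  # tree-child: every internal vertex has at least one child that is not a
  # reticulation vertex
  rets <- which(indeg == 2L)
  internal <- which(outdeg > 0L)
  for (v in internal) {
    ch <- e[e[, 1L] == v, 2L]
    if (all(ch %in% rets)) {
      abort("invalid network: not tree-child (all children of a vertex are reticulations)")
    }
  }
  invisible(net)
}

is_cyclic_digraph <- function(edges, nv) {
  indeg <- tabulate(edges[, 2L], nbins = nv)
  present <- sort(unique(as.integer(edges)))
  queue <- setdiff(which(indeg == 0L), setdiff(seq_len(nv), present))
  seen <- 0L
  indeg2 <- indeg
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    ch <- edges[edges[, 1L] == v, 2L]
    for (w in ch) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(present)
}

#' @export
print.rooted_network <- function(x, ...) {
  cat(sprintf(
    "<rooted_network: %d taxa, %d vertices, %d reticulation(s)>\n",
    sum(!is.na(x$labels)), x$nv, length(x$ret_pairs)
  ))
  cat("  taxa:", paste(sort(x$labels[!is.na(x$labels)]), collapse = ", "), "\n")
  cat("  eNewick:", write_enewick(x), "\n")
  invisible(x)
}

#' Taxon set of a network
#'
#' @param net a `rooted_network` or `semidirected_network`.
#' @return Sorted character vector of taxon names.
#' @export
taxa <- function(net) sort(net$labels[!is.na(net$labels)])

#' Number of reticulation vertices
#'
#' @param net a `rooted_network` or `semidirected_network`.
#' @return Integer count of in-degree-2 vertices.
#' @export
n_reticulations <- function(net) {
  if (inherits(net, "rooted_network")) {
    indeg <- tabulate(net$edges[, 2L], nbins = net$nv)
    sum(indeg == 2L)
  } else {
    length(ret_vertices(net))
  }
}
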