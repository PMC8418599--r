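#' Semi-directed networks
#'
#' A semi-directed network is the mixed graph obtained from a rooted binary
#' phylogenetic network by undirecting all non-reticulation edges,
#' suppressing degree-two vertices, and identifying parallel edges. Only
#' the two edges into each reticulation vertex stay directed. Leaf labels
#' are retained; the root is forgotten.
#'
#' @param edges two-column integer matrix (for directed rows: from, to with
#'   `to` the reticulation vertex).
#' @param directed logical vector, one entry per edge row.
#' @param labels character vector, one entry per vertex (`NA` internal).
#' @param ret_pairs optional named list: reticulation vertex id ->
#'   `c(e0 = row, e1 = row)` giving the kept-edge convention (`e1` is the
#'   edge retained with probability `delta`). Defaults to edge-row order.
#' @param validate check structural invariants.
#' @return An object of class `semidirected_network`.
#' @export
semidirected_network <- function(edges, directed, labels, ret_pairs = NULL,
                                 validate = TRUE) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  net <- structure(
    list(nv = length(labels), edges = edges, directed = as.logical(directed),
         labels = as.character(labels), ret_pairs = ret_pairs),
    class = "semidirected_network"
  )
  if (is.null(ret_pairs)) {
    rets <- ret_vertices(net)
    net$ret_pairs <- lapply(rets, function(v) {
      idx <- which(net$directed & net$edges[, 2L] == v)
      c(e0 = idx[1L], e1 = idx[2L])
    })
    names(net$ret_pairs) <- as.character(rets)
  }
  if (validate) validate_sd_structure(net)
  net
}

#' Reticulation vertices of a semi-directed network
#' @param net a `semidirected_network`.
#' @return Integer vertex ids with two incoming directed edges.
#' @export
ret_vertices <- function(net) {
  tgt <- net$edges[net$directed, 2L]
  as.integer(sort(unique(tgt[tabulate(tgt, nbins = net$nv)[tgt] == 2L])))
}

sd_degree <- function(net) {
  tabulate(net$edges[, 1L], nbins = net$nv) +
    tabulate(net$edges[, 2L], nbins = net$nv)
}

validate_sd_structure <- function(net) {
  deg <- sd_degree(net)
  leaves <- which(!is.na(net$labels))
  if (anyDuplicated(net$labels[leaves])) {
    abort("invalid network: leaf labels are not a bijection (duplicate taxon)")
  }
  if (net$nv > 2L && any(deg[leaves] != 1L)) {
    abort("invalid network: leaves must have degree 1")
  }
  internal <- which(is.na(net$labels))
  if (any(deg[internal] == 2L)) abort("invalid network: degree-2 vertex present")
  if (net$nv > 2L && any(deg[internal] != 3L)) {
    abort("invalid network: internal vertices must have degree 3")
  }
  key <- paste(pmin(net$edges[, 1L], net$edges[, 2L]),
               pmax(net$edges[, 1L], net$edges[, 2L]))
  if (anyDuplicated(key)) abort("invalid network: parallel edges present")
  tgt <- net$edges[net$directed, 2L]
  cnt <- table(tgt)
  if (any(cnt != 2L)) {
    abort("invalid network: directed edges must come in pairs into a reticulation vertex")
  }
  invisible(net)
}

#' @export
print.semidirected_network <- function(x, ...) {
  cat(sprintf(
    "<semidirected_network: %d taxa, %d vertices, %d reticulation(s)>\n",
    sum(!is.na(x$labels)), x$nv, length(ret_vertices(x))
  ))
  cat("  taxa:", paste(taxa(x), collapse = ", "), "\n")
  cat("  eNewick (canonical rooting):", write_enewick(root_network(x)), "\n")
  invisible(x)
}

# --- normalization of a mixed graph ------------------------------------

# state: list(edges, directed, labels, vid (original vertex ids),
# eid (original edge ids)). Repeatedly (a) undirects edges whose head has
# directed in-degree < 2, (b) prunes unlabeled vertices of degree <= 1,
# (c) identifies parallel edges, (d) suppresses degree-2 vertices, until a
# fixed point is reached.
normalize_mixed <- function(edges, directed, labels, eid = NULL) {
  vid <- seq_along(labels)
  if (is.null(eid)) eid <- seq_len(nrow(edges))
  repeat {
    changed <- FALSE
    nv <- length(labels)
    # (a) directions are only meaningful into in-degree-2 heads
    if (any(directed)) {
      tgt <- edges[, 2L]
      din <- tabulate(tgt[directed], nbins = nv)
      bad <- directed & din[tgt] < 2L
      if (any(bad)) {
        directed[bad] <- FALSE
        changed <- TRUE
      }
    }
    deg <- tabulate(edges[, 1L], nbins = nv) + tabulate(edges[, 2L], nbins = nv)
    # (b) prune dead ends
    drop_v <- which(is.na(labels) & deg <= 1L)
    # a reticulation that lost its outgoing side is a dead end too
    if (any(directed)) {
      din <- tabulate(edges[directed, 2L], nbins = nv)
      drop_v <- union(drop_v, which(is.na(labels) & deg == 2L & din == 2L))
    }
    if (length(drop_v) > 0L) {
      keep_e <- !(edges[, 1L] %in% drop_v | edges[, 2L] %in% drop_v)
      edges <- edges[keep_e, , drop = FALSE]
      directed <- directed[keep_e]
      eid <- eid[keep_e]
      keep_v <- setdiff(seq_len(nv), drop_v)
      remap <- rep(NA_integer_, nv)
      remap[keep_v] <- seq_along(keep_v)
      edges <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
      labels <- labels[keep_v]
      vid <- vid[keep_v]
      changed <- TRUE
      next
    }
    # (c) identify parallel edges
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    dup <- which(duplicated(key))
    if (length(dup) > 0L) {
      d <- dup[[1L]]
      first <- which(key == key[[d]])[[1L]]
      # if the pair was the two reticulation edges, the merged edge models
      # the convex sum delta*M + (1-delta)*M' and is no longer directed
      keep_e <- setdiff(seq_len(nrow(edges)), d)
      directed[first] <- directed[first] && directed[d] &&
        edges[first, 2L] == edges[d, 2L]
      edges <- edges[keep_e, , drop = FALSE]
      directed <- directed[keep_e]
      eid <- eid[keep_e]
      changed <- TRUE
      next
    }
    # (d) suppress one degree-2 unlabeled vertex
    v <- which(is.na(labels) & deg == 2L)
    if (length(v) > 0L) {
      v <- v[[1L]]
      inc <- which(edges[, 1L] == v | edges[, 2L] == v)
      e1 <- inc[[1L]]; e2 <- inc[[2L]]
      other <- function(e) if (edges[e, 1L] == v) edges[e, 2L] else edges[e, 1L]
      u <- other(e1); w <- other(e2)
      # direction survives only if one constituent points into a head != v
      if (directed[e1] && edges[e1, 2L] != v) {
        new_edge <- c(w, edges[e1, 2L]); new_dir <- TRUE; new_eid <- eid[e1]
      } else if (directed[e2] && edges[e2, 2L] != v) {
        new_edge <- c(u, edges[e2, 2L]); new_dir <- TRUE; new_eid <- eid[e2]
      } else {
        new_edge <- c(u, w); new_dir <- FALSE; new_eid <- eid[e1]
      }
      keep_e <- setdiff(seq_len(nrow(edges)), c(e1, e2))
      edges <- rbind(edges[keep_e, , drop = FALSE], new_edge)
      directed <- c(directed[keep_e], new_dir)
      eid <- c(eid[keep_e], new_eid)
      # v is now isolated; drop it
      keep_v <- setdiff(seq_along(labels), v)
      remap <- rep(NA_integer_, length(labels))
      remap[keep_v] <- seq_along(keep_v)
      edges <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
      labels <- labels[keep_v]
      vid <- vid[keep_v]
      changed <- TRUE
      next
    }
    if (!changed) break
  }
  list(edges = edges, directed = directed, labels = labels,
       vid = vid, eid = eid)
}

#' Unroot a network: the associated semi-directed network
#'
#' Undirects all non-reticulation edges, suppresses degree-two vertices
#' (including the old root) and identifies parallel edges. If the
#' identified pair was the two edges into a reticulation vertex, that
#' reticulation disappears and `r` drops by one.
#'
#' @param net a [rooted_network()].
#' @return A [semidirected_network()].
#' @examples
#' to_semidirected(parse_enewick("((a,b),(c,d));"))
#' @export
to_semidirected <- function(net) {
  stopifnot(inherits(net, "rooted_network"))
  indeg <- tabulate(net$edges[, 2L], nbins = net$nv)
  directed <- indeg[net$edges[, 2L]] == 2L
  st <- normalize_mixed(net$edges, directed, net$labels)
  out <- semidirected_network(st$edges, st$directed, st$labels,
                              ret_pairs = ret_pairs_from_eid(st, net$ret_pairs),
                              validate = FALSE)
  validate_sd_structure(out)
  out
}

# rebuild the e0/e1 designation after normalization using surviving
# original edge ids; reticulations whose original pair did not survive
# intact fall back to edge-row order
ret_pairs_from_eid <- function(st, orig_pairs) {
  tgt <- st$edges[st$directed, 2L]
  rets <- sort(unique(tgt))
  pairs <- lapply(rets, function(v) {
    idx <- which(st$directed & st$edges[, 2L] == v)
    roles <- vapply(idx, function(i) {
      e <- st$eid[[i]]
      for (p in orig_pairs) {
        if (!is.na(p[["e0"]]) && p[["e0"]] == e) return("e0")
        if (!is.na(p[["e1"]]) && p[["e1"]] == e) return("e1")
      }
      NA_character_
    }, character(1L))
    if (identical(sort(roles), c("e0", "e1"))) {
      c(e0 = idx[roles == "e0"], e1 = idx[roles == "e1"])
    } else {
      c(e0 = idx[1L], e1 = idx[2L])
    }
  })
  names(pairs) <- as.character(rets)
  pairs
}

# --- skeleton machinery -------------------------------------------------

as_igraph_skeleton <- function(net) {
  igraph::graph_from_edgelist(net$edges, directed = FALSE)
}

# cycles of a level-1 network: biconnected components with >= 3 vertices,
# returned as ordered vertex sequences (each starts at its smallest vertex)
sd_cycles <- function(net) {
  if (nrow(net$edges) == 0L) return(list())
  memo_get("cycles", net_key(net), function() sd_cycles_impl(net))
}

sd_cycles_impl <- function(net) {
  g <- as_igraph_skeleton(net)
  bc <- igraph::biconnected_components(g)
  out <- list()
  for (comp in bc$components) {
    vs <- as.integer(comp)
    if (length(vs) < 3L) next
    out[[length(out) + 1L]] <- order_cycle(net, vs)
  }
  # deterministic order: by smallest contained vertex
  out[order(vapply(out, min, 1L))]
}

order_cycle <- function(net, vs) {
  adj <- lapply(vs, function(v) {
    nb <- c(net$edges[net$edges[, 1L] == v, 2L], net$edges[net$edges[, 2L] == v, 1L])
    intersect(nb, vs)
  })
  names(adj) <- as.character(vs)
  start <- min(vs)
  prev <- -1L
  cur <- start
  path <- integer()
  repeat {
    path <- c(path, cur)
    nb <- adj[[as.character(cur)]]
    nxt <- setdiff(nb, prev)
    # start direction deterministically: toward the smaller neighbor
    if (length(nxt) > 1L) nxt <- min(nxt)
    if (nxt == start) break
    prev <- cur
    cur <- nxt
  }
  as.integer(path)
}

# vertices cut off from the rest by removing edge row `e` and taking the
# side of endpoint `from_v`
component_after_removal <- function(net, e, from_v) {
  m <- nrow(net$edges)
  keep <- setdiff(seq_len(m), e)
  adj <- vector("list", net$nv)
  for (i in keep) {
    a <- net$edges[i, 1L]; b <- net$edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(net$nv)
  queue <- from_v
  seen[from_v] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  which(seen)
}

# the cut edge hanging off reticulation h (its single undirected edge)
ret_pendant_edge <- function(net, h) {
  inc <- which((net$edges[, 1L] == h | net$edges[, 2L] == h) & !net$directed)
  stopifnot(length(inc) == 1L)
  inc
}

# --- rooting ------------------------------------------------------------

# edge rows that may be subdivided by a root: cut-edges not lying below any
# reticulation (if the root were below a reticulation h, the cycle through
# h could not be oriented away from the root)
valid_root_edges <- function(net) {
  cyc <- sd_cycles(net)
  on_cycle <- logical(nrow(net$edges))
  for (cv in cyc) {
    on_cycle <- on_cycle |
      (net$edges[, 1L] %in% cv & net$edges[, 2L] %in% cv)
  }
  bridges <- which(!on_cycle)
  bad <- logical(nrow(net$edges))
  for (h in ret_vertices(net)) {
    pe <- ret_pendant_edge(net, h)
    w <- setdiff(net$edges[pe, ], h)
    region <- component_after_removal(net, pe, w)
    bad[pe] <- TRUE
    bad <- bad | (net$edges[, 1L] %in% region & net$edges[, 2L] %in% region)
  }
  setdiff(bridges, which(bad))
}

# BFS distances in the mixed graph from a start vertex (directed edges
# traversable forward only)
mixed_bfs_dist <- function(edges, directed, nv, start) {
  adj <- vector("list", nv)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    if (!directed[i]) adj[[b]] <- c(adj[[b]], a)
  }
  dist <- rep(NA_integer_, nv)
  dist[start] <- 0L
  queue <- start
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

#' Root a semi-directed network
#'
#' Produces a rooted representative: the root subdivides a cut-edge chosen
#' so that all edges can be directed away from it while preserving
#' reticulation-edge directions. The canonical choice is the valid cut-edge
#' nearest the lexicographically smallest taxon. By Proposition-1-type
#' invariance the Markov model attached to the result does not depend on
#' this choice.
#'
#' @param net a [semidirected_network()].
#' @param at_edge optional edge row to subdivide instead of the canonical
#'   choice (must be a valid root edge).
#' @return A [rooted_network()] with an `sd_edge` attribute mapping each
#'   rooted edge row to the semi-directed edge row it came from (the two
#'   halves of the subdivided edge map to the same row).
#' @export
root_network <- function(net, at_edge = NULL) {
  stopifnot(inherits(net, "semidirected_network"))
  if (is.null(at_edge)) {
    return(memo_get("rooting", net_key(net), function() {
      root_network_impl(net, NULL)
    }))
  }
  root_network_impl(net, at_edge)
}

root_network_impl <- function(net, at_edge) {
  cand <- valid_root_edges(net)
  if (length(cand) == 0L) abort("network admits no valid rooting")
  if (is.null(at_edge)) {
    tx <- taxa(net)
    leaf <- which(net$labels == tx[[1L]])
    dist <- mixed_bfs_dist(net$edges, rep(FALSE, nrow(net$edges)), net$nv, leaf)
    edist <- pmin(dist[net$edges[cand, 1L]], dist[net$edges[cand, 2L]])
    at_edge <- cand[order(edist, cand)][[1L]]
  } else if (!(at_edge %in% cand)) {
    abort("at_edge is not a valid root edge")
  }
  u <- net$edges[at_edge, 1L]
  v <- net$edges[at_edge, 2L]
  rho <- net$nv + 1L
  keep <- setdiff(seq_len(nrow(net$edges)), at_edge)
  edges <- rbind(net$edges[keep, , drop = FALSE], c(rho, u), c(rho, v))
  directed <- c(net$directed[keep], FALSE, FALSE)
  sd_edge <- c(keep, at_edge, at_edge)
  labels <- c(net$labels, NA_character_)
  dist <- mixed_bfs_dist(edges, directed, rho, rho)
  if (anyNA(dist)) abort("network admits no valid rooting (unreachable part)")
  oriented <- edges
  for (i in seq_len(nrow(edges))) {
    if (directed[i]) next
    a <- edges[i, 1L]; b <- edges[i, 2L]
    if (dist[a] == dist[b]) abort("internal error: ambiguous edge orientation")
    if (dist[a] > dist[b]) oriented[i, ] <- c(b, a)
  }
  # e0/e1 roles carried over from the semi-directed pairs
  ret_pairs <- lapply(net$ret_pairs, function(p) {
    c(e0 = match(p[["e0"]], sd_edge), e1 = match(p[["e1"]], sd_edge))
  })
  names(ret_pairs) <- names(net$ret_pairs)
  out <- rooted_network(oriented, labels, rho, ret_pairs = ret_pairs)
  out$sd_edge <- sd_edge
  out
}

# --- equality -----------------------------------------------------------

#' Test whether two networks are the same leaf-labelled semi-directed network
#'
#' Equality is leaf-labelled isomorphism of the mixed graph. For level-1
#' networks the skeleton together with the set of marked reticulation
#' vertices determines the directed edges (the two cycle edges at each
#' reticulation point into it), so the test is a vertex-coloured graph
#' isomorphism with leaves coloured by their taxon.
#'
#' @param net1,net2 [semidirected_network()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
network_identical <- function(net1, net2) {
  tx <- taxa(net1)
  if (!identical(tx, taxa(net2))) return(FALSE)
  if (net1$nv != net2$nv || nrow(net1$edges) != nrow(net2$edges)) return(FALSE)
  r1 <- ret_vertices(net1); r2 <- ret_vertices(net2)
  if (length(r1) != length(r2)) return(FALSE)
  color <- function(net, rets) {
    cl <- integer(net$nv)
    cl[is.na(net$labels)] <- 1L
    cl[rets] <- 2L
    lf <- !is.na(net$labels)
    cl[lf] <- 2L + match(net$labels[lf], tx)
    cl
  }
  g1 <- as_igraph_skeleton(net1)
  g2 <- as_igraph_skeleton(net2)
  igraph::is_isomorphic_to(g1, g2, method = "vf2",
                           vertex.color1 = color(net1, r1),
                           vertex.color2 = color(net2, r2))
}

#' Relabel the taxa of a network
#'
#' @param net a `semidirected_network`.
#' @param perm named character vector mapping old taxon names to new ones.
#' @return The relabelled network.
#' @export
relabel_network <- function(net, perm) {
  lf <- !is.na(net$labels)
  out <- net
  out$labels[lf] <- unname(perm[net$labels[lf]])
  if (anyNA(out$labels[lf]) || anyDuplicated(out$labels[lf])) {
    abort("perm must be a bijection on the taxon set")
  }
  out
}

#' Structural report for a semi-directed network
#'
#' @param net a [semidirected_network()].
#' @return A one-row tibble with columns `n_leaves`, `r` (number of
#'   reticulations), `level` (max reticulations per biconnected component),
#'   `is_binary`, `triangle_free`, `rootable`.
#' @examples
#' validate_network(to_semidirected(parse_enewick("((a,b),(c,d));")))
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "semidirected_network"))
  deg <- sd_degree(net)
  leaves <- which(!is.na(net$labels))
  internal <- which(is.na(net$labels))
  is_binary <- all(deg[leaves] == 1L) &&
    (net$nv <= 2L || all(deg[internal] == 3L))
  rets <- ret_vertices(net)
  cyc <- sd_cycles(net)
  level <- if (length(cyc) == 0L) 0L else {
    max(vapply(cyc, function(cv) sum(rets %in% cv), 1L))
  }
  tibble(
    n_leaves = length(leaves),
    r = length(rets),
    level = level,
    is_binary = is_binary,
    triangle_free = all(vapply(cyc, length, 1L) >= 4L),
    rootable = length(valid_root_edges(net)) > 0L
  )
}
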