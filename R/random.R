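#' Random level-1 semi-directed network
#'
#' Generates a random valid level-1 (optionally triangle-free)
#' semi-directed network: a random unrooted binary tree is grown by leaf
#' insertion, then each reticulation cycle is created by replacing a
#' random path of unused internal vertices with a cycle, reattaching the
#' hanging edges in random cyclic order and picking a random reticulation
#' vertex. This is a convenient fixture generator, not a statistically
#' uniform sampler. Deterministic given `seed`.
#'
#' @param n number of taxa (labels `t1`, `t2`, ...; at least 2).
#' @param r number of reticulations.
#' @param seed integer seed.
#' @param triangle_free if `TRUE` (default) all cycles have length >= 4.
#' @param labels optional character vector of `n` taxon names.
#' @return A [semidirected_network()].
#' @examples
#' net <- random_network(8, r = 2, seed = 42)
#' validate_network(net)
#' @export
random_network <- function(n, r, seed, triangle_free = TRUE, labels = NULL) {
  if (n < 2L || r < 0L) abort("need n >= 2 and r >= 0")
  min_m <- if (triangle_free) 2L else 1L
  if (r > 0L && (n < 3L || min_m * r > n - 2L)) {
    abort(sprintf("infeasible: a level-1 network with %d cycle(s)%s needs more leaves",
                  r, if (triangle_free) " of length >= 4" else ""))
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  labels <- sort(labels)
  with_seed(seed, {
    for (attempt in seq_len(400L)) {
      net <- try_random_network(n, r, labels, min_m)
      if (!is.null(net)) return(net)
    }
    abort("could not generate a valid network for these settings")
  })
}

try_random_network <- function(n, r, labels, min_m) {
  # --- random unrooted binary tree by leaf insertion ---
  if (n == 2L) {
    edges <- cbind(1L, 2L)
    vlab <- labels
  } else {
    vlab <- c(labels[1:3], NA_character_)
    edges <- rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L))
    for (i in seq_len(n - 3L)) {
      e <- sample.int(nrow(edges), 1L)
      a <- edges[e, 1L]; b <- edges[e, 2L]
      vlab <- c(vlab, NA_character_, labels[3L + i])
      w <- length(vlab) - 1L
      lf <- length(vlab)
      edges <- rbind(edges[-e, , drop = FALSE], c(a, w), c(w, b), c(w, lf))
    }
  }
  directed <- rep(FALSE, nrow(edges))
  used <- logical(length(vlab))     # vertices on a cycle already
  ret_of <- integer()               # reticulation vertex per cycle
  cyc_sets <- list()                # vertex ids of each inserted cycle
  # --- insert r cycles ---
  for (ci in seq_len(r)) {
    internal <- which(is.na(vlab) & !used)
    max_m <- length(internal)
    if (max_m < min_m) return(NULL)
    m_choices <- seq.int(min_m, max_m)
    m <- if (length(m_choices) == 1L) m_choices else {
      sample(m_choices, 1L, prob = 0.55^m_choices)
    }
    path <- random_internal_path(edges, vlab, used, m)
    if (is.null(path)) return(NULL)
    # hanging edges of the path, each as (row, outside endpoint)
    on_path_row <- (edges[, 1L] %in% path) & (edges[, 2L] %in% path)
    ext <- list()
    for (i in seq_len(nrow(edges))) {
      if (on_path_row[[i]]) next
      a <- edges[i, 1L]; b <- edges[i, 2L]
      if (a %in% path) ext[[length(ext) + 1L]] <- c(i, b)
      else if (b %in% path) ext[[length(ext) + 1L]] <- c(i, a)
    }
    k <- m + 2L
    stopifnot(length(ext) == k)
    ext <- ext[sample.int(k)]
    base <- length(vlab)
    vlab <- c(vlab, rep(NA_character_, k))
    cyc <- base + seq_len(k)
    keep <- !on_path_row & !(edges[, 1L] %in% path) & !(edges[, 2L] %in% path)
    new_edges <- edges[keep, , drop = FALSE]
    directed <- directed[keep]
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      new_edges <- rbind(new_edges, c(cyc[[i]], cyc[[j]]))
      directed <- c(directed, FALSE)
      new_edges <- rbind(new_edges, c(cyc[[i]], ext[[i]][[2L]]))
      directed <- c(directed, FALSE)
    }
    edges <- new_edges
    used[path] <- TRUE   # replaced (deleted) vertices are no longer usable
    used <- c(used, rep(TRUE, k))
    cyc_sets[[length(cyc_sets) + 1L]] <- cyc
    ret_of <- c(ret_of, cyc[[sample.int(k, 1L)]])
  }
  # orient the two cycle edges at each reticulation
  for (ci in seq_along(ret_of)) {
    rv <- ret_of[[ci]]
    cset <- cyc_sets[[ci]]
    ring <- which((edges[, 1L] == rv | edges[, 2L] == rv) &
                    edges[, 1L] %in% cset & edges[, 2L] %in% cset)
    for (row in ring) {
      if (edges[row, 2L] != rv) edges[row, ] <- rev(edges[row, ])
      directed[row] <- TRUE
    }
  }
  # compact: drop deleted path vertices
  present <- sort(unique(as.integer(edges)))
  remap <- rep(NA_integer_, length(vlab))
  remap[present] <- seq_along(present)
  edges <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
  net <- semidirected_network(edges, directed, vlab[present], validate = FALSE)
  ok <- tryCatch({
    validate_sd_structure(net)
    length(valid_root_edges(net)) > 0L
  }, error = function(e) FALSE)
  if (!ok) return(NULL)
  net
}

# random simple path of m unused internal vertices
random_internal_path <- function(edges, vlab, used, m) {
  ok_v <- which(is.na(vlab) & !used)
  if (length(ok_v) < m) return(NULL)
  adj <- vector("list", length(vlab))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (try in seq_len(30L)) {
    path <- if (length(ok_v) == 1L) ok_v else sample(ok_v, 1L)
    while (length(path) < m) {
      nb <- setdiff(intersect(adj[[path[[length(path)]]]], ok_v), path)
      if (length(nb) == 0L) break
      path <- c(path, if (length(nb) == 1L) nb else sample(nb, 1L))
    }
    if (length(path) == m) return(path)
  }
  NULL
}
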