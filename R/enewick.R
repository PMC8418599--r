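#' Parse an extended Newick (eNewick) string
#'
#' Reads a rooted binary phylogenetic network from eNewick text. Hybrid
#' (reticulation) vertices are written with `#H<k>`-style tags; each hybrid
#' tag must appear exactly twice, and at most one occurrence may carry a
#' subtree. The parent edge of the *first* occurrence (in reading order) is
#' taken as the reticulation edge `e1`, the edge kept with probability
#' `delta` in the network Markov model; the second occurrence's parent edge
#' is `e0`.
#'
#' @param text a single eNewick string, e.g. `"((a,(b)#H1),(#H1,c));"`.
#' @return A [rooted_network()].
#' @examples
#' parse_enewick("((a,b),(c,d));")
#' parse_enewick("((a,(b)#H1),(#H1,c));")
#' @export
parse_enewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(trimws(text), "")[[1L]]
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  st$labels <- character()
  st$edges_from <- integer()
  st$edges_to <- integer()
  st$hybrids <- list()         # tag -> vertex id
  st$hybrid_children <- list() # tag -> TRUE once a subtree was attached
  st$dead <- integer()         # vertices merged away into a hybrid vertex

  peek <- function() if (st$pos <= length(chars)) chars[[st$pos]] else ""
  advance <- function() st$pos <- st$pos + 1L
  fail <- function(msg) {
    abort(sprintf("eNewick syntax error at position %d: %s", st$pos, msg),
          class = "seminet_parse_error")
  }
  new_vertex <- function(label = NA_character_) {
    st$labels <- c(st$labels, label)
    length(st$labels)
  }
  add_edge <- function(from, to) {
    st$edges_from <- c(st$edges_from, from)
    st$edges_to <- c(st$edges_to, to)
  }
  read_name <- function() {
    out <- character()
    while (grepl("[A-Za-z0-9_.\\-]", peek())) {
      out <- c(out, peek())
      advance()
    }
    paste0(out, collapse = "")
  }

  # returns the vertex id of the parsed subtree; edges to children are
  # appended the moment each child completes, so the in-edges of a hybrid
  # vertex end up in reading order of its occurrences
  parse_subtree <- function() {
    has_children <- FALSE
    v <- NA_integer_
    if (peek() == "(") {
      has_children <- TRUE
      v <- new_vertex()
      advance()
      repeat {
        ch <- parse_subtree()
        add_edge(v, ch)
        if (peek() == ",") {
          advance()
        } else if (peek() == ")") {
          advance()
          break
        } else {
          fail("expected ',' or ')'")
        }
      }
    }
    name <- read_name()
    tag <- NULL
    if (peek() == "#") {
      advance()
      tag <- read_name()
      if (!nzchar(tag)) fail("empty hybrid tag after '#'")
    }
    if (!has_children && !nzchar(name) && is.null(tag)) {
      fail("expected a leaf label, '(' or hybrid tag")
    }
    if (!is.null(tag)) {
      if (is.null(st$hybrids[[tag]])) {
        if (!has_children) v <- new_vertex()
        st$hybrids[[tag]] <- v
        st$hybrid_children[[tag]] <- has_children
      } else {
        hv <- st$hybrids[[tag]]
        if (has_children) {
          if (isTRUE(st$hybrid_children[[tag]])) {
            fail(sprintf("hybrid '#%s' has a subtree at more than one occurrence", tag))
          }
          st$hybrid_children[[tag]] <- TRUE
          # merge the eagerly created vertex into the hybrid vertex
          st$edges_from[st$edges_from == v] <- hv
          st$dead <- c(st$dead, v)
        }
        v <- hv
      }
      return(v)
    }
    if (!has_children) v <- new_vertex(name)
    v
  }

  root <- parse_subtree()
  if (peek() != ";") fail("expected ';'")
  advance()
  if (st$pos <= length(chars)) fail("trailing characters after ';'")

  for (tag in names(st$hybrids)) {
    if (sum(st$edges_to == st$hybrids[[tag]]) != 2L) {
      abort(sprintf("hybrid '#%s' must appear exactly twice", tag),
            class = "seminet_parse_error")
    }
    if (!isTRUE(st$hybrid_children[[tag]])) {
      abort(sprintf("hybrid '#%s' has no subtree at any occurrence", tag),
            class = "seminet_parse_error")
    }
  }

  # compact vertex ids (drop merged-away vertices)
  keep <- setdiff(seq_along(st$labels), st$dead)
  remap <- rep(NA_integer_, length(st$labels))
  remap[keep] <- seq_along(keep)
  edges <- cbind(remap[st$edges_from], remap[st$edges_to])
  labels <- st$labels[keep]
  root <- remap[root]
  # e1 = in-edge from the first occurrence in reading order (earlier row)
  ret_pairs <- lapply(st$hybrids, function(v) {
    idx <- which(edges[, 2L] == remap[v])
    c(e0 = idx[2L], e1 = idx[1L])
  })
  names(ret_pairs) <- as.character(vapply(st$hybrids, function(v) remap[v], 1L))
  rooted_network(edges, labels, root, ret_pairs = ret_pairs)
}

#' Serialize a rooted network to eNewick
#'
#' The full subtree below a reticulation vertex is written at its first
#' occurrence in the traversal; the second occurrence is a bare `#H<k>` tag.
#'
#' @param net a [rooted_network()].
#' @return A single eNewick string.
#' @export
write_enewick <- function(net) {
  stopifnot(inherits(net, "rooted_network"))
  e <- net$edges
  indeg <- tabulate(e[, 2L], nbins = net$nv)
  rets <- which(indeg == 2L)
  hyb_id <- setNames(seq_along(rets), rets)
  emitted <- new.env(parent = emptyenv())

  emit <- function(v) {
    tag <- ""
    if (v %in% rets) {
      tag <- paste0("#H", hyb_id[[as.character(v)]])
      if (!is.null(emitted[[as.character(v)]])) return(tag)
      emitted[[as.character(v)]] <- TRUE
    }
    ch <- e[e[, 1L] == v, 2L]
    if (length(ch) == 0L) {
      return(paste0(net$labels[v], tag))
    }
    paste0("(", paste(vapply(ch, emit, character(1L)), collapse = ","), ")", tag)
  }
  paste0(emit(net$root), ";")
}
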