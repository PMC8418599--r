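#' Splits of a semi-directed network
#'
#' One split per cut-edge (edges not lying on a cycle). Trivial splits
#' (a singleton side) are included and flagged. `side_a` is the side
#' containing the lexicographically smallest taxon; taxa within a side are
#' sorted.
#'
#' @param net a [semidirected_network()].
#' @return A tibble with list-columns `side_a`, `side_b`, logical
#'   `trivial`, and the integer cut-`edge` row.
#' @examples
#' splits(to_semidirected(parse_enewick("((a,b),(c,d));")))
#' @export
splits <- function(net) {
  stopifnot(inherits(net, "semidirected_network"))
  cyc <- sd_cycles(net)
  on_cycle <- logical(nrow(net$edges))
  for (cv in cyc) {
    on_cycle <- on_cycle | (net$edges[, 1L] %in% cv & net$edges[, 2L] %in% cv)
  }
  bridges <- which(!on_cycle)
  tx <- taxa(net)
  rows <- map(bridges, function(e) {
    side <- component_after_removal(net, e, net$edges[e, 1L])
    a <- sort(net$labels[intersect(side, which(!is.na(net$labels)))])
    b <- setdiff(tx, a)
    if (!(tx[[1L]] %in% a)) {
      tmp <- a; a <- b; b <- tmp
    }
    tibble(side_a = list(a), side_b = list(b),
           trivial = min(length(a), length(b)) < 2L, edge = e)
  })
  out <- bind_rows(rows)
  out[order(map_chr(out$side_a, paste, collapse = ","),
            map_chr(out$side_b, paste, collapse = ",")), ]
}

split_key <- function(a, b) {
  paste(paste(sort(a), collapse = ","), paste(sort(b), collapse = ","), sep = "|")
}

# does `net` have a split with X as one side?
has_split <- function(net, X) {
  X <- sort(X)
  sp <- splits(net)
  any(map_lgl(sp$side_a, identical, X)) || any(map_lgl(sp$side_b, identical, X))
}

#' Common and conflicting splits of two networks
#'
#' Two splits X-Y (in `net1`) and A-B (in `net2`) conflict if all four
#' pairwise intersections of sides are non-empty; a trivial split can
#' never conflict. `common_splits()` returns the splits present in both
#' networks.
#'
#' @param net1,net2 networks on the same taxon set.
#' @return `conflicting_splits()`: `NULL` if no conflicting pair exists,
#'   else a list with elements `split1` and `split2`, each a list with
#'   `side_a`/`side_b`. `common_splits()`: a tibble like [splits()] without
#'   the `edge` column.
#' @export
conflicting_splits <- function(net1, net2) {
  if (!identical(taxa(net1), taxa(net2))) abort("networks must share a taxon set")
  s1 <- filter(splits(net1), !.data$trivial)
  s2 <- filter(splits(net2), !.data$trivial)
  for (i in seq_len(nrow(s1))) {
    for (j in seq_len(nrow(s2))) {
      X <- s1$side_a[[i]]; Y <- s1$side_b[[i]]
      A <- s2$side_a[[j]]; B <- s2$side_b[[j]]
      if (length(intersect(X, A)) > 0L && length(intersect(X, B)) > 0L &&
          length(intersect(Y, A)) > 0L && length(intersect(Y, B)) > 0L) {
        return(list(split1 = list(side_a = X, side_b = Y),
                    split2 = list(side_a = A, side_b = B)))
      }
    }
  }
  NULL
}

#' @rdname conflicting_splits
#' @export
common_splits <- function(net1, net2) {
  if (!identical(taxa(net1), taxa(net2))) abort("networks must share a taxon set")
  s1 <- splits(net1)
  s2 <- splits(net2)
  k1 <- map_chr(seq_len(nrow(s1)), function(i) split_key(s1$side_a[[i]], s1$side_b[[i]]))
  k2 <- map_chr(seq_len(nrow(s2)), function(i) split_key(s2$side_a[[i]], s2$side_b[[i]]))
  out <- s1[k1 %in% k2, c("side_a", "side_b", "trivial")]
  out
}
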