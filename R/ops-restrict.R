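#' Restriction of a semi-directed network to a taxon subset
#'
#' `N|_A` is the union of all directed paths between leaves of `A` (with
#' undirected edges traversable both ways), with degree-two vertices then
#' suppressed and parallel edges identified. Computed on a rooted
#' representative: an edge lies on a leaf-to-leaf path exactly when its
#' head still reaches a leaf of `A` in the rooted DAG, and the stem above
#' the last common ancestor collapses during normalization. Cycles may
#' shorten: a 4-cycle can become a triangle, and a cycle reduced to two
#' parallel edges collapses, its reticulation disappearing.
#'
#' @param net a [semidirected_network()].
#' @param taxa_keep subset of [taxa()] of size at least 2.
#' @return The restricted [semidirected_network()].
#' @examples
#' n <- to_semidirected(parse_enewick("(((a,(b)#H1),(#H1,c)),d);"))
#' restriction(n, c("a", "c", "d"))
#' @export
restriction <- function(net, taxa_keep) {
  stopifnot(inherits(net, "semidirected_network"))
  tx <- taxa(net)
  taxa_keep <- sort(unique(taxa_keep))
  if (!all(taxa_keep %in% tx)) abort("taxa_keep must be a subset of the taxon set")
  if (length(taxa_keep) < 2L) abort("restriction needs at least 2 taxa")
  if (identical(taxa_keep, tx)) return(net)
  rn <- root_network(net)
  nv <- rn$nv
  e <- rn$edges
  # vertices from which a kept leaf is reachable (reverse reachability)
  desc <- logical(nv)
  desc[which(rn$labels %in% taxa_keep)] <- TRUE
  queue <- which(desc)
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    parents <- e[e[, 2L] == v, 1L]
    new <- parents[!desc[parents]]
    desc[new] <- TRUE
    queue <- c(queue, new)
  }
  keep_e <- desc[e[, 2L]]
  keep_v <- which(desc)
  remap <- rep(NA_integer_, nv)
  remap[keep_v] <- seq_along(keep_v)
  edges <- cbind(remap[e[keep_e, 1L]], remap[e[keep_e, 2L]])
  labels <- rn$labels[keep_v]
  labels[!(labels %in% taxa_keep)] <- NA_character_
  indeg <- tabulate(edges[, 2L], nbins = length(keep_v))
  directed <- indeg[edges[, 2L]] == 2L
  st <- normalize_mixed(edges, directed, labels)
  out <- semidirected_network(st$edges, st$directed, st$labels, validate = FALSE)
  validate_sd_structure(out)
  out
}

#' Quotient of a network by one side of a split
#'
#' For a split X-Y of `N`, the quotient `N/X` is `N` restricted to
#' `{x} union Y` for an arbitrary `x` in `X` (the unrooted skeleton does
#' not depend on the choice; the lexicographically smallest member is
#' used). Reticulation numbers are additive over the two quotients:
#' `r(N/X) + r(N/Y) = r(N)`.
#'
#' @param net a [semidirected_network()].
#' @param side character vector: one side of a split of `net`.
#' @return The quotient [semidirected_network()].
#' @export
quotient <- function(net, side) {
  side <- sort(unique(side))
  if (!has_split(net, side)) {
    abort("`side` is not one side of a split of the network")
  }
  other <- setdiff(taxa(net), side)
  restriction(net, c(side[[1L]], other))
}
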