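#' Displayed trees of a network
#'
#' A network with r reticulations displays 2^r rooted trees: for each
#' binary vector sigma, delete edge `e0_i` when `sigma_i = 0` (keeping
#' `e1_i`, which happens with probability `delta_i`), and `e1_i` when
#' `sigma_i = 1`. The tree weight is
#' `prod_i delta_i^(1-sigma_i) (1-delta_i)^sigma_i`; weights sum to one.
#'
#' @param net a [rooted_network()] or [semidirected_network()].
#' @param weights tibble (`ret`, `delta`) as in [sample_parameters()];
#'   may be `NULL` for a tree.
#' @return A tibble with columns `sigma` (list of 0/1 vectors), `dropped`
#'   (list of deleted edge rows of `net`), `kept` (list of retained edge
#'   rows) and `weight`.
#' @export
displayed_trees <- function(net, weights = NULL) {
  pairs <- net$ret_pairs %||% list()
  rets <- as.integer(names(pairs))
  ord <- order(rets)
  rets <- rets[ord]
  pairs <- pairs[ord]
  r <- length(pairs)
  delta <- if (r == 0L) numeric() else {
    stopifnot(!is.null(weights))
    weights$delta[match(rets, weights$ret)]
  }
  m <- nrow(net$edges)
  skel <- memo_get("displayed", net_key(net), function() {
    sigmas <- if (r == 0L) list(integer()) else {
      lapply(asplit(as.matrix(expand.grid(rep(list(0:1), r))), 1L), as.integer)
    }
    dropped <- map(sigmas, function(sig) {
      map_int(seq_len(r), function(i) {
        if (sig[[i]] == 0L) pairs[[i]][["e0"]] else pairs[[i]][["e1"]]
      })
    })
    list(sigma = sigmas, dropped = dropped,
         kept = map(dropped, function(d) setdiff(seq_len(m), d)))
  })
  weight <- map_dbl(skel$sigma, function(sig) {
    if (r == 0L) 1 else prod(delta^(1L - sig) * (1 - delta)^sig)
  })
  tibble(sigma = skel$sigma, dropped = skel$dropped,
         kept = skel$kept, weight = weight)
}

# matrices per rooted edge row from probability-domain params; for a
# semi-directed input the rooted representative has one subdivided edge
# whose second half gets the identity matrix
rooted_edge_matrices <- function(rn, params) {
  m <- nrow(rn$edges)
  if (is.null(rn$sd_edge)) {
    if (nrow(params$edges) != m) {
      abort("params do not match the network's edge set")
    }
    idx <- match(seq_len(m), params$edges$edge)
  } else {
    idx <- match(rn$sd_edge, params$edges$edge)
    dupe <- duplicated(rn$sd_edge)
    idx[dupe] <- NA_integer_ # identity on the second half of the root edge
    if (anyNA(idx[!dupe])) abort("params do not match the network's edge set")
  }
  lapply(seq_len(m), function(e) {
    i <- idx[[e]]
    if (is.na(i)) diag(4) else {
      transition_matrix(params$edges$alpha[[i]], params$edges$beta[[i]],
                        params$edges$gamma[[i]], params$edges$delta[[i]])
    }
  })
}

# joint leaf distribution of one displayed tree by pruning DP; returns the
# 4^n vector in sorted-taxon order (first taxon = most significant digit)
tree_joint_distribution <- function(rn, kept, mats) {
  e <- rn$edges
  child_rows <- vector("list", rn$nv)
  for (row in kept) {
    v <- e[row, 1L]
    child_rows[[v]] <- c(child_rows[[v]], row)
  }
  rec <- function(v) {
    rows <- child_rows[[v]]
    if (length(rows) == 0L) {
      lab <- rn$labels[[v]]
      return(list(mat = diag(4),
                  leaves = if (is.na(lab)) character() else lab))
    }
    acc <- NULL
    leaves <- character()
    for (row in rows) {
      sub <- rec(e[row, 2L])
      a <- mats[[row]] %*% sub$mat
      if (is.null(acc)) {
        acc <- a
        leaves <- sub$leaves
      } else if (length(sub$leaves) == 0L) {
        # dangling branch with no leaves below: marginalises to row sums
        acc <- acc * as.vector(a %*% rep(1, ncol(a)))
      } else if (length(leaves) == 0L) {
        acc <- a * as.vector(acc %*% rep(1, ncol(acc)))
        leaves <- sub$leaves
      } else {
        na <- ncol(acc); nb <- ncol(a)
        acc <- acc[, rep(seq_len(na), each = nb), drop = FALSE] *
          a[, rep(seq_len(nb), times = na), drop = FALSE]
        leaves <- c(leaves, sub$leaves)
      }
    }
    list(mat = acc, leaves = leaves)
  }
  top <- rec(rn$root)
  p <- colSums(top$mat) / 4
  ord <- top$leaves
  tx <- sort(ord)
  n <- length(ord)
  if (identical(ord, tx)) return(p)
  arr <- array(p, dim = rep(4L, n))
  # array dim i corresponds to leaf ord[n + 1 - i]
  perm <- n + 1L - match(tx[n:1], ord)
  as.vector(aperm(arr, perm))
}

spd_vector <- function(rn, params) {
  mats <- rooted_edge_matrices(rn, params)
  dt <- displayed_trees(rn, params$weights)
  n <- length(taxa(rn))
  p <- numeric(4L^n)
  for (i in seq_len(nrow(dt))) {
    p <- p + dt$weight[[i]] * tree_joint_distribution(rn, dt$kept[[i]], mats)
  }
  p
}

#' Site-pattern distribution of a network Markov model
#'
#' The probability of each leaf site-pattern is the reticulation-weighted
#' sum, over the 2^r displayed trees, of the tree probabilities obtained
#' by marginalising the uniform root distribution and per-edge transition
#' matrices over all internal-state assignments. For a semi-directed
#' network a canonical rooted representative is used; the result does not
#' depend on the rooting.
#'
#' @param net a [rooted_network()] or [semidirected_network()].
#' @param params a `seminet_params` object keyed by `net`'s edges.
#' @return A tibble with columns `pattern` (e.g. `"AGCT"`, taxa in sorted
#'   order, patterns lexicographic in base order A, G, C, T) and
#'   `probability`; attributes `taxa` and `constraint`.
#' @examples
#' net <- to_semidirected(parse_enewick("((a,b),(c,d));"))
#' p <- site_pattern_distribution(net, sample_parameters(net, "JC", 1))
#' sum(p$probability)
#' @export
site_pattern_distribution <- function(net, params) {
  rn <- if (inherits(net, "semidirected_network")) root_network(net) else net
  p <- spd_vector(rn, params)
  tx <- taxa(rn)
  out <- tibble(pattern = pattern_strings(length(tx)), probability = p)
  attr(out, "taxa") <- tx
  attr(out, "constraint") <- params$constraint
  out
}

#' Simulate a multiple sequence alignment from a network model
#'
#' Draws `length` i.i.d. site-patterns from the model's site-pattern
#' distribution and assembles one sequence per taxon. Optionally writes a
#' FASTA file.
#'
#' @param net a [rooted_network()] or [semidirected_network()].
#' @param params a `seminet_params` object.
#' @param length number of sites (>= 1).
#' @param seed integer seed.
#' @param file optional path; if given the alignment is written as FASTA.
#' @return A tibble (`taxon`, `sequence`), invisibly when `file` is given.
#' @export
simulate_alignment <- function(net, params, length, seed, file = NULL) {
  if (length < 1L) abort("alignment length must be >= 1")
  rn <- if (inherits(net, "semidirected_network")) root_network(net) else net
  p <- spd_vector(rn, params)
  tx <- taxa(rn)
  n <- length(tx)
  codes <- pattern_codes(n)
  idx <- with_seed(seed, sample.int(4L^n, size = length, replace = TRUE, prob = p))
  seqs <- vapply(seq_len(n), function(j) {
    paste0(BASES[codes[idx, j] + 1L], collapse = "")
  }, character(1L))
  out <- tibble(taxon = tx, sequence = seqs)
  if (!is.null(file)) {
    writeLines(paste0(">", out$taxon, "\n", out$sequence), con = file)
    return(invisible(out))
  }
  out
}
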