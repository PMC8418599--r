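# apply the 4x4 character matrix along every taxon axis of a 4^n vector
hadamard_apply <- function(v, n, inverse = FALSE) {
  H <- hadamard4()
  if (inverse) H <- H / 4
  for (i in seq_len(n)) {
    v <- as.vector(t(H %*% matrix(v, nrow = 4L)))
  }
  v
}

#' Fourier-Hadamard transform of a site-pattern distribution
#'
#' Applies the character transform of (Z2 x Z2)^n under the base/group
#' assignment A=(0,0), G=(1,0), C=(0,1), T=(1,1):
#' `q_g = sum_w prod_j chi(g_j, w_j) p_w`. For a distribution from a
#' group-based model the resulting q-coordinates vanish off the zero
#' group-sum set and `q_{AA...A} = 1`. The transform is an involution up
#' to scaling; [inverse_fourier()] recovers `p` exactly.
#'
#' @param p a tibble as returned by [site_pattern_distribution()] (columns
#'   `pattern`, `probability`), or a bare numeric vector of length 4^n.
#' @return A tibble (`pattern`, `q`) with the same attributes.
#' @examples
#' net <- to_semidirected(parse_enewick("((a,b),(c,d));"))
#' q <- fourier_transform(site_pattern_distribution(net, sample_parameters(net, "JC", 1)))
#' q$q[q$pattern == "AAAA"]
#' @export
fourier_transform <- function(p) {
  v <- if (is.data.frame(p)) p$probability else p
  n <- round(log(length(v), 4))
  if (4L^n != length(v)) abort("length must be a power of 4")
  q <- hadamard_apply(v, n)
  out <- tibble(pattern = pattern_strings(n), q = q)
  attr(out, "taxa") <- attr(p, "taxa")
  out
}

#' @rdname fourier_transform
#' @param q a tibble (`pattern`, `q`) or numeric vector of length 4^n.
#' @export
inverse_fourier <- function(q) {
  v <- if (is.data.frame(q)) q$q else q
  n <- round(log(length(v), 4))
  if (4L^n != length(v)) abort("length must be a power of 4")
  p <- hadamard_apply(v, n, inverse = TRUE)
  out <- tibble(pattern = pattern_strings(n), probability = p)
  attr(out, "taxa") <- attr(q, "taxa")
  out
}

# for every kept edge of a displayed tree (a spanning tree of the
# semi-directed graph), the set of leaf positions (in sorted-taxon order)
# on one side of the split the edge induces; an edge separating no leaves
# contributes the empty set (its Fourier factor is a_A = 1)
edge_sides <- function(net, kept) {
  memo_get("sides", paste(net_key(net), paste(kept, collapse = ",")),
           function() edge_sides_impl(net, kept))
}

edge_sides_impl <- function(net, kept) {
  tx <- taxa(net)
  adj <- vector("list", net$nv)
  for (row in kept) {
    a <- net$edges[row, 1L]; b <- net$edges[row, 2L]
    adj[[a]] <- c(adj[[a]], row)
    adj[[b]] <- c(adj[[b]], row)
  }
  lapply(kept, function(row) {
    a <- net$edges[row, 1L]; b <- net$edges[row, 2L]
    # component of b after removing `row` (the tree side away from a)
    seen <- logical(net$nv)
    seen[b] <- TRUE
    queue <- b
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (r2 in adj[[v]]) {
        if (r2 == row) next
        w <- if (net$edges[r2, 1L] == v) net$edges[r2, 2L] else net$edges[r2, 1L]
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    labs <- net$labels[seen & !is.na(net$labels)]
    sort(match(labs, tx))
  })
}

# q-coordinates as a plain 4^n vector; `value` selects ordinary (exact
# dyadic) arithmetic or arithmetic mod PIT_PRIME
q_vector <- function(net, fparams, modular = FALSE) {
  stopifnot(inherits(net, "semidirected_network"))
  tx <- taxa(net)
  n <- length(tx)
  codes <- pattern_codes(n)
  dt <- displayed_trees(net, fparams$weights)
  emat <- as.matrix(fparams$edges[, c("a_A", "a_G", "a_C", "a_T")])
  q <- numeric(4L^n)
  p <- PIT_PRIME
  rets <- sort(as.integer(names(net$ret_pairs %||% list())))
  deltas <- fparams$weights$delta[match(rets, fparams$weights$ret)]
  for (i in seq_len(nrow(dt))) {
    kept <- dt$kept[[i]]
    sides <- edge_sides(net, kept)
    w <- if (modular) {
      # recompute the reticulation weight mod p (residues are too large
      # for the plain product in displayed_trees)
      sig <- dt$sigma[[i]]
      acc <- 1
      for (k in seq_along(sig)) {
        f <- if (sig[[k]] == 0L) deltas[[k]] else (1 - deltas[[k]])
        acc <- mod_mul(acc, f %% p, p)
      }
      acc
    } else {
      dt$weight[[i]]
    }
    term <- rep(w, 4L^n)
    for (j in seq_along(kept)) {
      row <- kept[[j]]
      a <- emat[match(row, fparams$edges$edge), ]
      s <- xor_reduce(codes, sides[[j]])
      f <- a[s + 1L]
      term <- if (modular) mod_mul(term, f %% p, p) else term * f
    }
    q <- if (modular) mod_add(q, term, p) else q + term
  }
  total <- xor_reduce(codes, seq_len(n))
  q[total != 0L] <- 0
  unname(q)
}

#' Fourier parameterization of a network model
#'
#' Computes the q-coordinates of the model directly from Fourier edge
#' parameters: for each displayed tree, each retained edge `e`
#' contributes the factor `a^e` indexed by the group sum of the pattern
#' over one side of the split `e` induces in that tree (on the zero-sum
#' set the two sides give the same index); `q_w` is the
#' reticulation-weighted sum of these monomials over all 2^r displayed
#' trees, and 0 whenever the pattern's total group sum is nonzero.
#'
#' @param net a [semidirected_network()].
#' @param fparams a `seminet_fparams` object (see [as_fourier_params()]
#'   and [sample_fourier_parameters()]) keyed by `net`'s edge rows.
#' @return A tibble (`pattern`, `q`) with attribute `taxa`.
#' @export
fourier_parameterization <- function(net, fparams) {
  stopifnot(inherits(fparams, "seminet_fparams"))
  q <- q_vector(net, fparams)
  out <- tibble(pattern = pattern_strings(length(taxa(net))), q = q)
  attr(out, "taxa") <- taxa(net)
  out
}
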