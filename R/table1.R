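CANON4 <- c("a", "b", "c", "d")

# relabel a 4-leaf network onto canonical labels positionally (sorted
# taxon i -> CANON4[i]); vanishing verdicts are label-equivariant, so the
# catalog vanishing table only ever needs to be computed on CANON4
canonical4 <- function(net) {
  tx <- taxa(net)
  stopifnot(length(tx) == 4L)
  relabel_network(net, setNames(CANON4, tx))
}

# index of `net` (on CANON4) in the canonical catalog
catalog_index <- function(net, cat4 = enumerate_4leaf_catalog(CANON4)) {
  tag <- classify4(net)
  for (j in which(cat4$tag == tag)) {
    if (network_identical(net, cat4$network[[j]])) return(j)
  }
  abort("internal error: network not found in the 4-leaf catalog")
}

# ids of closure polynomials vanishing on column j2 but (witnessed) not
# on column j1: each certifies V_{net1} not-subset-of V_{net2}
noncontainment_witnesses <- function(V, j1, j2) {
  rownames(V)[V[, j2] & !V[, j1]]
}

#' Compare two 4-leaf networks via distinguishing invariants
#'
#' Classifies an ordered pair of distinct 4-leaf level-1 networks by
#' searching the relabeling closure of the six distinguishing invariants
#' for witnesses of non-containment in each direction: a polynomial that
#' vanishes identically on one network's variety (symbolic verdict) but
#' not on the other's (nonzero modular evaluation) certifies that the
#' second variety is not contained in the first.
#'
#' @param net1,net2 distinct [semidirected_network()]s on the same four
#'   taxa.
#' @param constraint `"JC"`, `"K2P"` or `"K3P"`.
#' @return An object of class `pair_verdict4`: list with `outcome` (one
#'   of `"DISTINGUISHABLE"`, `"LEFT_NOT_SUBSET"` (V1 not in V2),
#'   `"RIGHT_NOT_SUBSET"`, `"SKELETON_CONDITIONAL"` (no witness either
#'   way; for triangle and double-triangle pairs sharing a skeleton the
#'   varieties coincide)), witness id vectors `witnesses_12`,
#'   `witnesses_21`, the `constraint`, `tags`, and `same_skeleton`.
#' @examples
#' t1 <- quartet_tree("a", "b", "c", "d")
#' t2 <- quartet_tree("a", "c", "b", "d")
#' pair_verdict(t1, t2, "JC")$outcome
#' @export
pair_verdict <- function(net1, net2, constraint) {
  constraint <- constraint_kind(constraint)
  if (!identical(taxa(net1), taxa(net2))) abort("networks must share a taxon set")
  if (network_identical(net1, net2)) {
    abort("networks must be distinct")
  }
  c1 <- canonical4(net1)
  c2 <- canonical4(net2)
  V <- catalog_vanishing(CANON4, constraint)
  cat4 <- attr(V, "catalog")
  j1 <- catalog_index(c1, cat4)
  j2 <- catalog_index(c2, cat4)
  w12 <- noncontainment_witnesses(V, j1, j2)  # V1 not subset of V2
  w21 <- noncontainment_witnesses(V, j2, j1)
  outcome <- if (length(w12) > 0L && length(w21) > 0L) {
    "DISTINGUISHABLE"
  } else if (length(w12) > 0L) {
    "LEFT_NOT_SUBSET"
  } else if (length(w21) > 0L) {
    "RIGHT_NOT_SUBSET"
  } else {
    "SKELETON_CONDITIONAL"
  }
  structure(
    list(outcome = outcome, witnesses_12 = w12, witnesses_21 = w21,
         constraint = constraint,
         tags = c(classify4(net1), classify4(net2)),
         same_skeleton = skeleton_identical(net1, net2),
         taxa = taxa(net1)),
    class = "pair_verdict4"
  )
}

#' @export
print.pair_verdict4 <- function(x, ...) {
  cat(sprintf("<pair_verdict4 [%s]: %s vs %s -> %s>\n",
              x$constraint, x$tags[[1L]], x$tags[[2L]], x$outcome))
  if (length(x$witnesses_12) > 0L) {
    cat("  V1 <!= V2 witnesses:", paste(head(x$witnesses_12, 4L), collapse = ", "),
        if (length(x$witnesses_12) > 4L) "..." else "", "\n")
  }
  if (length(x$witnesses_21) > 0L) {
    cat("  V2 <!= V1 witnesses:", paste(head(x$witnesses_21, 4L), collapse = ", "),
        if (length(x$witnesses_21) > 4L) "..." else "", "\n")
  }
  invisible(x)
}

# leaf-labelled skeleton equality (reticulation marks ignored)
skeleton_identical <- function(net1, net2) {
  tx <- taxa(net1)
  if (!identical(tx, taxa(net2))) return(FALSE)
  if (net1$nv != net2$nv || nrow(net1$edges) != nrow(net2$edges)) return(FALSE)
  color <- function(net) {
    cl <- integer(net$nv)
    cl[is.na(net$labels)] <- 1L
    lf <- !is.na(net$labels)
    cl[lf] <- 1L + match(net$labels[lf], tx)
    cl
  }
  igraph::is_isomorphic_to(as_igraph_skeleton(net1), as_igraph_skeleton(net2),
                           method = "vf2",
                           vertex.color1 = color(net1),
                           vertex.color2 = color(net2))
}

#' Recompute the 4-leaf verdict grid
#'
#' Classifies every ordered pair of distinct 4-leaf catalog networks by
#' shape (quartet tree Q, single triangle, double triangle DT, 4-cycle)
#' and aggregates the invariant-witness verdicts into a 4x4 grid: `"√"`
#' when every pair in the cell is distinguishable (both non-containments
#' witnessed), `"⊈"` / `"⊉"` when only the corresponding direction is
#' witnessed for every pair, and `"~"` when pairs with different
#' leaf-labelled skeletons are distinguishable while same-skeleton pairs
#' share a variety. The grid is computed entirely from vanishing
#' verdicts, not transcribed.
#'
#' @param constraint `"JC"`, `"K2P"` or `"K3P"`.
#' @return A 4x4 character matrix with dimnames
#'   `Q`, `TRIANGLE`, `DOUBLE_TRIANGLE`, `FOUR_CYCLE` (rows = first
#'   network, columns = second).
#' @export
table1_matrix <- function(constraint) {
  constraint <- constraint_kind(constraint)
  V <- catalog_vanishing(CANON4, constraint)
  cat4 <- attr(V, "catalog")
  tags <- c("Q", "TRIANGLE", "DOUBLE_TRIANGLE", "FOUR_CYCLE")
  skel_key <- map_chr(cat4$network, function(n) skeleton_signature(n))
  out <- matrix("", 4L, 4L, dimnames = list(tags, tags))
  for (t1 in tags) {
    for (t2 in tags) {
      i1 <- which(cat4$tag == t1)
      i2 <- which(cat4$tag == t2)
      all12 <- TRUE; all21 <- TRUE; mixed_ok <- TRUE
      for (j1 in i1) {
        for (j2 in i2) {
          if (j1 == j2) next
          w12 <- length(noncontainment_witnesses(V, j1, j2)) > 0L
          w21 <- length(noncontainment_witnesses(V, j2, j1)) > 0L
          all12 <- all12 && w12
          all21 <- all21 && w21
          same_skel <- skel_key[[j1]] == skel_key[[j2]]
          mixed_ok <- mixed_ok &&
            ((same_skel && !w12 && !w21) || (!same_skel && w12 && w21))
        }
      }
      out[t1, t2] <- if (all12 && all21) "√"
      else if (all12) "⊈"
      else if (all21) "⊉"
      else if (mixed_ok) "~"
      else "?"
    }
  }
  out
}

# canonical string of the leaf-labelled skeleton, for grouping
skeleton_signature <- function(net) {
  memo_get("skelsig", net_key(net), function() {
    sp <- splits(net)
    ntv <- sp[!sp$trivial, ]
    cycs <- sd_cycles(net)
    cyc_sig <- map_chr(cycs, function(cv) {
      part <- cycle_partition(net, cv)
      # skeleton only: blocks in cycle order, canonical rotation/reflection
      blocks <- map_chr(part$block, paste, collapse = ",")
      k <- length(blocks)
      cands <- character()
      for (s in seq_len(k)) {
        rot <- blocks[((seq_len(k) + s - 2L) %% k) + 1L]
        cands <- c(cands, paste(rot, collapse = "|"),
                   paste(rev(rot), collapse = "|"))
      }
      min(cands)
    })
    paste(
      paste(sort(map_chr(seq_len(nrow(ntv)), function(i) {
        split_key(ntv$side_a[[i]], ntv$side_b[[i]])
      })), collapse = ";"),
      paste(sort(cyc_sig), collapse = ";"),
      sep = "#"
    )
  })
}
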