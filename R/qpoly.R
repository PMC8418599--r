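#' Polynomials in Fourier coordinates
#'
#' A `qpolynomial` is a sparse polynomial in the q-coordinates of 4-leaf
#' site patterns: a list of terms, each a rational coefficient and a
#' multiset of pattern variables such as `"CTTC"`.
#'
#' @param terms list of `list(coef = <number>, vars = <character vector>)`.
#' @param id optional identifier.
#' @return An object of class `qpolynomial`.
#' @export
qpolynomial <- function(terms, id = NULL) {
  stopifnot(all(map_lgl(terms, function(t) {
    is.numeric(t$coef) && is.character(t$vars) &&
      all(nchar(t$vars) == nchar(t$vars[[1L]])) &&
      all(strsplit(paste(t$vars, collapse = ""), "")[[1L]] %in% BASES)
  })))
  structure(list(terms = terms, id = id), class = "qpolynomial")
}

#' @export
print.qpolynomial <- function(x, ...) {
  s <- map_chr(x$terms, function(t) {
    mono <- paste0("q_", sort(t$vars), collapse = "*")
    co <- if (t$coef == 1) "" else if (t$coef == -1) "-" else paste0(t$coef, "*")
    paste0(co, mono)
  })
  out <- paste(s, collapse = " + ")
  out <- gsub("\\+ -", "- ", out)
  cat(if (!is.null(x$id)) paste0(x$id, " = ") else "", out, "\n", sep = "")
  invisible(x)
}

qp_vars <- function(poly) sort(unique(unlist(map(poly$terms, "vars"))))

qp_degree <- function(poly) max(map_int(poly$terms, function(t) length(t$vars)))

#' The six distinguishing invariants for 4-leaf networks
#'
#' Returns the six polynomial invariants, exactly as printed, that
#' together separate the 4-leaf level-1 network varieties under the JC,
#' K2P and K3P constraints: g1 and g2 handle single-triangle and tree
#' varieties, g3 double-triangle skeletons, and g4-g6 the 4-cycle versus
#' double-triangle comparisons. Variables are indexed by 4-leaf site
#' patterns in sorted taxon order.
#'
#' @return A named list of six [qpolynomial()] objects `g1`..`g6`.
#' @examples
#' builtin_invariants()$g2
#' @export
builtin_invariants <- function() {
  mk <- function(id, ...) {
    spec <- list(...)
    qpolynomial(map(spec, function(s) {
      list(coef = s[[1L]], vars = unlist(s[-1L]))
    }), id = id)
  }
  list(
    g1 = mk("g1",
      list(1, "ATTA", "CCGG", "GATC"),
      list(-1, "AAGG", "CTTC", "GCTA")),
    g2 = mk("g2",
      list(1, "CTTC"),
      list(-1, "GCGC")),
    g3 = mk("g3",
      list(1, "CAGT", "GTCA", "TGAC"),
      list(-1, "CACA", "GTGT", "TGAC"),
      list(-1, "CAGT", "GTAC", "TGCA"),
      list(1, "CAAC", "GTGT", "TGCA"),
      list(1, "CACA", "GTAC", "TGGT"),
      list(-1, "CAAC", "GTCA", "TGGT")),
    g4 = mk("g4",
      list(1, "AACC", "CGCG", "GAGA", "TAAT"),
      list(-1, "AACC", "CGAT", "GAGA", "TACG"),
      list(1, "AACC", "CAGT", "GGAA", "TACG"),
      list(-1, "AAAA", "CAGT", "GGCC", "TACG")),
    g5 = mk("g5",
      list(1, "AAAA", "GACT", "GCGC"),
      list(-1, "AAGG", "TAAT", "TGCA")),
    g6 = mk("g6",
      list(1, "AAGG", "GATC", "TAAT"),
      list(-1, "AATT", "GAAG", "TAGC"))
  )
}

#' Evaluate a q-polynomial at a point
#'
#' @param poly a [qpolynomial()].
#' @param q a tibble as from [fourier_transform()] /
#'   [fourier_parameterization()] (columns `pattern`, `q`), or a numeric
#'   vector named by patterns, or an unnamed vector of length 4^4 in
#'   lexicographic pattern order.
#' @return The value (exact when the inputs are exact dyadic rationals).
#' @export
evaluate_qpoly <- function(poly, q) {
  qv <- q_lookup(q)
  total <- 0
  for (t in poly$terms) {
    idx <- match(t$vars, names(qv))
    if (anyNA(idx)) abort("q does not provide all variables of the polynomial")
    total <- total + t$coef * prod(qv[idx])
  }
  total
}

evaluate_qpoly_mod <- function(poly, qv_named, p = PIT_PRIME) {
  total <- 0
  for (t in poly$terms) {
    acc <- t$coef %% p
    for (v in t$vars) acc <- mod_mul(acc, qv_named[[v]] %% p, p)
    total <- mod_add(total, acc, p)
  }
  total
}

q_lookup <- function(q) {
  if (is.data.frame(q)) {
    return(setNames(q$q, q$pattern))
  }
  if (!is.null(names(q))) return(q)
  setNames(q, pattern_strings(round(log(length(q), 4))))
}

# action of a taxon permutation on a q-polynomial: position j of each
# pattern variable is replaced by position perm[j]; f applied to a
# relabelled network's coordinates equals the permuted f on the original
permute_qpoly <- function(poly, perm) {
  qpolynomial(map(poly$terms, function(t) {
    list(coef = t$coef, vars = map_chr(t$vars, function(v) {
      paste0(strsplit(v, "")[[1L]][perm], collapse = "")
    }))
  }), id = paste0(poly$id %||% "f", ".", paste(perm, collapse = "")))
}

# canonical string for deduplication
qp_key <- function(poly) {
  s <- sort(map_chr(poly$terms, function(t) {
    paste0(t$coef, ":", paste(sort(t$vars), collapse = "*"))
  }))
  paste(s, collapse = " + ")
}
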