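#' Model constraints: JC, K2P, K3P
#'
#' All three constraints restrict the symmetric K3P transition-matrix
#' template with rows/columns ordered A, G, C, T:
#' \preformatted{
#'   alpha beta  gamma delta
#'   beta  alpha delta gamma
#'   gamma delta alpha beta
#'   delta gamma beta  alpha
#' }
#' K2P (in the group-based convention used throughout: the Fourier
#' parameters indexed by the group elements C and T coincide) additionally
#' imposes beta = delta, and JC imposes beta = gamma = delta. The root
#' distribution is uniform.
#'
#' @param x constraint name, case-insensitive.
#' @return Canonical constraint string `"JC"`, `"K2P"` or `"K3P"`.
#' @export
constraint_kind <- function(x) {
  x <- toupper(x)
  if (!x %in% c("JC", "K2P", "K3P")) abort("constraint must be JC, K2P or K3P")
  x
}

#' Build a K3P-template transition matrix
#'
#' @param alpha,beta,gamma,delta entries of the first row (A->A, A->G,
#'   A->C, A->T); rows must sum to one.
#' @return A 4x4 stochastic matrix with `M[i, j] = m[code(i) xor code(j)]`.
#' @export
transition_matrix <- function(alpha, beta, gamma, delta) {
  m <- c(alpha, beta, gamma, delta)
  out <- outer(0:3, 0:3, function(i, j) m[bitwXor(i, j) + 1L])
  dimnames(out) <- list(BASES, BASES)
  out
}

#' Sample numerical model parameters for a network
#'
#' Draws one transition matrix per edge (satisfying the chosen constraint)
#' and one reticulation weight `delta` in (0, 1) per reticulation vertex.
#' With `exact = TRUE` all values are dyadic rationals with denominator 8,
#' so that every arithmetic operation downstream (site-pattern
#' probabilities, Hadamard transform, Fourier monomials) is carried out
#' without any floating-point rounding; equality of the two
#' parameterizations can then be tested exactly.
#'
#' @param net a [semidirected_network()] or [rooted_network()]; matrices
#'   are keyed by its edge rows.
#' @param constraint `"JC"`, `"K2P"` or `"K3P"`.
#' @param seed integer seed.
#' @param exact draw dyadic rationals (denominator 8) instead of
#'   continuous values.
#' @return An object of class `seminet_params`: a list with `constraint`,
#'   `edges` (tibble `edge`, `alpha`, `beta`, `gamma`, `delta`) and
#'   `weights` (tibble `ret`, `delta`).
#' @export
sample_parameters <- function(net, constraint, seed, exact = FALSE) {
  constraint <- constraint_kind(constraint)
  m <- nrow(net$edges)
  rets <- as.integer(names(net$ret_pairs %||% list()))
  with_seed(seed, {
    draw <- function(k) {
      if (exact) sample(1:2, k, replace = TRUE) / 8 else runif(k, 0.02, 0.22)
    }
    b <- draw(m)
    g <- if (constraint == "JC") b else draw(m)
    d <- switch(constraint, JC = b, K2P = b, K3P = draw(m))
    w <- tibble(
      ret = rets,
      delta = if (exact) sample(1:7, length(rets), replace = TRUE) / 8 else {
        runif(length(rets), 0.05, 0.95)
      }
    )
    structure(
      list(constraint = constraint,
           edges = tibble(edge = seq_len(m), alpha = 1 - b - g - d,
                          beta = b, gamma = g, delta = d),
           weights = w, exact = exact),
      class = "seminet_params"
    )
  })
}

#' Map probability-domain parameters to Fourier edge parameters
#'
#' Applies the character transform of Z2 x Z2 to each edge's matrix
#' entries: `a_A = alpha+beta+gamma+delta = 1`,
#' `a_G = alpha-beta+gamma-delta`, `a_C = alpha+beta-gamma-delta`,
#' `a_T = alpha-beta-gamma+delta`. Under JC this forces
#' `a_G = a_C = a_T`; under K2P (beta = delta) it forces `a_C = a_T`.
#'
#' @param params a `seminet_params` object.
#' @return An object of class `seminet_fparams` with `edges` (tibble
#'   `edge`, `a_A`, `a_G`, `a_C`, `a_T`) and the same `weights`.
#' @export
as_fourier_params <- function(params) {
  stopifnot(inherits(params, "seminet_params"))
  e <- params$edges
  structure(
    list(
      constraint = params$constraint,
      edges = tibble(
        edge = e$edge,
        a_A = e$alpha + e$beta + e$gamma + e$delta,
        a_G = e$alpha - e$beta + e$gamma - e$delta,
        a_C = e$alpha + e$beta - e$gamma - e$delta,
        a_T = e$alpha - e$beta - e$gamma + e$delta
      ),
      weights = params$weights
    ),
    class = "seminet_fparams"
  )
}

#' Sample Fourier-domain edge parameters directly
#'
#' Used for evaluating invariants on a network variety at generic points:
#' variety membership is an algebraic question, so the sampled values need
#' not come from stochastic matrices. `mode = "modular"` draws integer
#' residues for exact polynomial identity testing mod a large prime.
#'
#' @param net a [semidirected_network()].
#' @param constraint `"JC"`, `"K2P"` or `"K3P"` (constraint equalities are
#'   imposed on the Fourier parameters).
#' @param seed integer seed.
#' @param mode `"unit"` for values in (0, 1), `"modular"` for residues.
#' @return A `seminet_fparams` object.
#' @export
sample_fourier_parameters <- function(net, constraint, seed,
                                      mode = c("unit", "modular")) {
  constraint <- constraint_kind(constraint)
  mode <- match.arg(mode)
  m <- nrow(net$edges)
  rets <- as.integer(names(net$ret_pairs %||% list()))
  with_seed(seed, {
    draw <- function(k) {
      if (mode == "modular") sample.int(PIT_PRIME - 1L, k, replace = TRUE) else {
        runif(k, 0.1, 0.95)
      }
    }
    g <- draw(m)
    c_ <- if (constraint == "JC") g else draw(m)
    t_ <- switch(constraint, JC = g, K2P = c_, K3P = draw(m))
    structure(
      list(constraint = constraint,
           edges = tibble(edge = seq_len(m), a_A = 1, a_G = g,
                          a_C = c_, a_T = t_),
           weights = tibble(ret = rets, delta = draw(length(rets))),
           mode = mode),
      class = "seminet_fparams"
    )
  })
}
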