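# Minimal sparse multivariate polynomial arithmetic over the integers,
# used for exact symbolic vanishing tests. A polynomial is a list with
# `coef` (numeric vector of integer values; exact in doubles at the
# magnitudes arising here) and `expo` (nterms x nvars integer exponent
# matrix). The variable universe is fixed by the caller.

mp_zero <- function(nvars) {
  list(coef = numeric(0), expo = matrix(0L, nrow = 0L, ncol = nvars))
}

mp_const <- function(c, nvars) {
  if (c == 0) return(mp_zero(nvars))
  list(coef = c, expo = matrix(0L, nrow = 1L, ncol = nvars))
}

mp_monomial <- function(coef, expo) {
  list(coef = coef, expo = matrix(as.integer(expo), nrow = 1L))
}

mp_collect <- function(p) {
  if (length(p$coef) <= 1L) {
    keep <- p$coef != 0
    return(list(coef = p$coef[keep], expo = p$expo[keep, , drop = FALSE]))
  }
  key <- do.call(paste, c(asplit(p$expo, 2L), sep = ","))
  coef <- rowsum(p$coef, key)
  first <- !duplicated(key)
  expo <- p$expo[first, , drop = FALSE]
  ord <- match(sort(unique(key)), key[first])
  coef <- as.vector(coef)            # rowsum sorts by key
  keep <- coef != 0
  list(coef = coef[keep], expo = expo[ord, , drop = FALSE][keep, , drop = FALSE])
}

mp_add <- function(a, b) {
  mp_collect(list(coef = c(a$coef, b$coef), expo = rbind(a$expo, b$expo)))
}

mp_scale <- function(a, c) {
  list(coef = a$coef * c, expo = a$expo)
}

mp_mul <- function(a, b) {
  na <- length(a$coef); nb <- length(b$coef)
  if (na == 0L || nb == 0L) return(mp_zero(ncol(a$expo)))
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  mp_collect(list(coef = a$coef[ia] * b$coef[ib],
                  expo = a$expo[ia, , drop = FALSE] + b$expo[ib, , drop = FALSE]))
}

mp_is_zero <- function(a) length(mp_collect(a)$coef) == 0L

# product of a list of polynomials, smallest first to keep intermediates
# small
mp_prod <- function(ps) {
  ps <- ps[order(vapply(ps, function(p) length(p$coef), 1L))]
  Reduce(mp_mul, ps)
}
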