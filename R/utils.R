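# DNA bases in the fixed order used everywhere: patterns are enumerated
# lexicographically in this base order, taxa in sorted-label order.
BASES <- c("A", "G", "C", "T")

# Group assignment A=(0,0), G=(1,0), C=(0,1), T=(1,1), encoded as the
# integers 0:3 so that group addition in Z2 x Z2 is bitwise XOR.
base_code <- function(x) match(x, BASES) - 1L

# character pairing chi_g(h) = (-1)^(g . h); with the encoding above the
# dot product is the parity of bitwAnd(g, h)
chi_sign <- function(g, h) {
  1L - 2L * (bitwAnd(bitwAnd(g, h), 1L) + bitwAnd(bitwShiftR(bitwAnd(g, h), 1L), 1L)) %% 2L
}

# 4x4 character matrix H[g+1, h+1] = chi_g(h); H %*% H == 4 I
hadamard4 <- function() {
  outer(0:3, 0:3, function(g, h) chi_sign(g, h))
}

# all 4^n site patterns as an integer code matrix (4^n rows, n cols),
# row i = pattern with index i, first taxon most significant digit;
# ordering is lexicographic in base order A,G,C,T
pattern_codes <- function(n) {
  stopifnot(n >= 1)
  m <- 4L^n
  out <- matrix(0L, nrow = m, ncol = n)
  for (j in seq_len(n)) {
    out[, j] <- bitwAnd(bitwShiftR(seq_len(m) - 1L, 2L * (n - j)), 3L)
  }
  out
}

pattern_strings <- function(n) {
  codes <- pattern_codes(n)
  apply(codes, 1L, function(row) paste0(BASES[row + 1L], collapse = ""))
}

# XOR-fold of columns of an integer matrix (group sum of selected taxa)
xor_reduce <- function(mat, cols) {
  if (length(cols) == 0L) {
    return(rep(0L, nrow(mat)))
  }
  acc <- mat[, cols[1L]]
  for (j in cols[-1L]) acc <- bitwXor(acc, mat[, j])
  acc
}

# run code with a deterministic RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# cheap structural key for memoising pure graph computations
net_key <- function(net) {
  paste(net$nv, paste(net$labels, collapse = ","),
        paste(net$edges, collapse = ","),
        paste(as.integer(net$directed), collapse = ""), sep = ";")
}

memo_get <- function(store, key, compute) {
  if (is.null(the[[store]])) the[[store]] <- new.env(parent = emptyenv(), hash = TRUE)
  env <- the[[store]]
  hit <- env[[key]]
  if (!is.null(hit)) return(hit)
  val <- compute()
  env[[key]] <- val
  val
}

# prime below 2^26: products of two residues stay below 2^52 and are exact
# in double arithmetic, so modular evaluation is exact
PIT_PRIME <- 67108859

mod_mul <- function(a, b, p = PIT_PRIME) (a * b) %% p
mod_add <- function(a, b, p = PIT_PRIME) (a + b) %% p
mod_pow <- function(a, k, p = PIT_PRIME) {
  r <- rep(1, length(a))
  a <- a %% p
  while (k > 0) {
    if (k %% 2 == 1) r <- mod_mul(r, a, p)
    a <- mod_mul(a, a, p)
    k <- k %/% 2
  }
  r
}
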