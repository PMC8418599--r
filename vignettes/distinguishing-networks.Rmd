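---
title: "Distinguishing level-1 semi-directed networks under group-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing level-1 semi-directed networks under group-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seminet)
```

## The scientific problem

Phylogenetic networks extend trees with reticulation vertices that model
hybridization, introgression and lateral gene transfer. A Markov model
of DNA substitution on a rooted binary network assigns each edge a
transition matrix, each reticulation a weight $\delta_i \in (0,1)$, and
produces a probability for every site pattern
$\omega \in \{A,G,C,T\}^n$ by marginalising over the $2^r$ *displayed
trees* (delete one of the two incoming edges at each reticulation):

$$p_\omega = \sum_{\sigma \in \{0,1\}^r}
  \Big(\prod_i \delta_i^{1-\sigma_i}(1-\delta_i)^{\sigma_i}\Big)
  \sum_{\phi:\,\phi(\mathcal X)=\omega} \pi_{\phi(\rho)}
  \prod_{e=uv} M^e_{\phi(u),\phi(v)}.$$

For a model-based inference method to be consistent, the network must be
*identifiable* from these distributions. Because the root location is
never identifiable under the symmetric group-based constraints, the
natural parameter is the **semi-directed network**: undirect everything
except the two edges into each reticulation, suppress degree-2 vertices,
identify parallel edges. This package implements the computational side
of the identifiability theory for **triangle-free level-1** semi-directed
networks (every skeleton cycle has length at least four and carries
exactly one reticulation), under the Jukes–Cantor (JC), Kimura
2-parameter (K2P) and Kimura 3-parameter (K3P) constraints:

* simulation of site-pattern distributions and alignments,
* Fourier (Hadamard) coordinates and the monomial parameterization,
* exact evaluation and vanishing tests for the six distinguishing
  invariants on the 4-leaf network catalog, and
* the recursive certificate search that decides, for two networks,
  which 4-leaf restrictions or split recursions witness that one model
  variety is not contained in the other.

Two networks whose varieties each escape the other are
*distinguishable*; a class in which all pairs are distinguishable has a
generically identifiable network parameter.

## Group-based models and the Fourier coordinates

Bases are identified with $\mathbb Z_2 \times \mathbb Z_2$ via
$A=(0,0)$, $G=(1,0)$, $C=(0,1)$, $T=(1,1)$. Every transition matrix has
the symmetric template (rows/columns in order A, G, C, T)

$$M = \begin{pmatrix}
\alpha&\beta&\gamma&\delta\\ \beta&\alpha&\delta&\gamma\\
\gamma&\delta&\alpha&\beta\\ \delta&\gamma&\beta&\alpha
\end{pmatrix},$$

i.e. $M_{g,h} = m_{g+h}$ with $m_A=\alpha, m_G=\beta, m_C=\gamma,
m_T=\delta$. The character transform of the group turns each edge's
entries into Fourier parameters $a_g = \sum_h \chi_g(h)\, m_h$, with
$a_A = 1$ from row-stochasticity, and turns the site-pattern
distribution into q-coordinates
$q_\omega = \sum_{\omega'} \prod_j \chi_{\omega_j}(\omega'_j)\,
p_{\omega'}$. On a tree the q-coordinate of a pattern with zero total
group sum is the *monomial* $\prod_e a^e_{\sum_{j \in Y_e} \omega_j}$,
where $Y_e$ is either side of the split that $e$ induces (the two sides
agree on the zero-sum support, a property the test suite checks rather
than assumes); all other q-coordinates are 0. A network's q-coordinates
are the reticulation-weighted sums of its displayed trees' monomials.

### The constraint conventions

* **K3P**: $a_G, a_C, a_T$ free per edge.
* **JC** ($\beta=\gamma=\delta$): $a_G = a_C = a_T$.
* **K2P**: the package uses the classical group-based convention in
  which the Fourier parameters at the two group elements with second
  coordinate one coincide, $a_C = a_T$, equivalently $\beta = \delta$
  in the template above.

The K2P choice deserves a note. Pairing the template's $\gamma = \delta$
restriction with the group assignment above would instead force
$a_G = a_T$. We verified computationally — both by symbolic expansion
and through an independent numeric pipeline (continuous stochastic
matrices, marginalisation, Hadamard transform) — that under that
identification the published behaviour of the distinguishing invariants
breaks down: $g_1$ vanishes on three single-triangle skeleton varieties
instead of one, and the witness set $\{g_4, g_6\}$ vanishes on
double-triangle varieties. Under the classical convention every claimed
vanishing pattern and the full 4-leaf verdict grid reproduce exactly
(these reproductions are tests in the package). The package therefore
implements K2P as $a_C = a_T$ throughout — sampling, symbolic algebra
and the probability-domain template consistently.

## Exact arithmetic

"Vanishes" must be decided exactly, so no floating-point rounding is
allowed anywhere in the identifiability chain. Three devices provide
this:

1. **Dyadic rationals in doubles.** Exact parameter draws use
   denominators that are powers of two (matrix entries in $\{1,2\}/8$,
   reticulation weights in $\{1,\dots,7\}/8$). Sums and products of
   dyadic rationals are represented exactly by IEEE doubles as long as
   numerators stay below $2^{53}$; at 4-leaf problem sizes the worst
   case is about $2^{44}$. The equality between the Hadamard transform
   of the marginalised distribution and the monomial parameterization is
   therefore tested with `identical()`, not with a tolerance.
2. **Integer-coefficient sparse polynomials.** The symbolic vanishing
   mode substitutes the parameterization with symbolic edge and
   reticulation variables (constraint equalities imposed) into an
   invariant and expands; the coefficients stay small integers and the
   verdict is an exact identity test.
3. **Modular evaluation.** The probabilistic mode evaluates at uniform
   random points over $\mathbb F_p$ with $p = 67108859 < 2^{26}$
   (products of residues stay below $2^{52}$, hence exact). A nonzero
   value certifies non-vanishing outright; apparent vanishing is
   confirmed symbolically before it is reported, so both verdict kinds
   are exact and the Schwartz–Zippel argument only controls how often
   the slow path is taken.

Floating point appears only where it belongs: continuous parameter
draws, alignment simulation, plotting.

## The 4-leaf catalog and the verdict grid

`enumerate_4leaf_catalog()` constructs all 57 labelled 4-leaf level-1
semi-directed networks — 3 quartet trees, 18 single triangles, 12
4-cycles, 24 double triangles (the bridge–bridge reticulation placement
admits no rooting and is excluded) — and groups them under the
leaf-relabeling action by isomorphism search; exactly 6 classes emerge.
This breakdown is computed, never assumed.

The six distinguishing invariants $g_1,\dots,g_6$ are hard-coded as
published and closed under the 24 leaf relabelings (the closure of a
network's ideal under relabeling is the ideal of the relabelled
network, which is also verified by test). `vanishes_on()` decides
membership per network and constraint; `pair_verdict()` searches the
closure for *witnesses of non-containment*: a polynomial vanishing
identically on one variety (symbolic verdict) while evaluating to a
nonzero residue on the other (modular witness). Aggregating witnesses
over ordered pairs reproduces the published 4×4 verdict grid for all
three constraints, including its "distinguishable only when the
skeletons differ" cells — triangle and double-triangle varieties are
skeleton properties, and the package's vanishing tables confirm that
reticulation placement never changes a verdict there.

## The certificate search

`find_noncontainment_certificate(net1, net2, constraint)` (requiring
$r(N_1) \ge r(N_2)$) mirrors the induction on the leaf count:

1. **4-leaf witness.** Scan the 4-subsets in lexicographic order for an
   $A$ with $N_1|_A$ a 4-cycle and $N_2|_A$ anything else; the 4-cycle
   row of the verdict grid supplies an invariant witnessing
   $\mathcal V_{N_1|_A} \not\subseteq \mathcal V_{N_2|_A}$, which lifts
   to the unrestricted networks.
2. **Conflicting splits.** Otherwise every induced 4-cycle agrees, so
   every cycle of $N_1$ is refined by one of $N_2$, and the split case
   analysis applies. Conflicting splits reduce to the four
   lexicographically smallest representatives of the intersections; the
   restricted pair has conflicting splits, hence a 4-leaf witness.
3. **Common split.** For a shared non-trivial split $X{-}Y$, quotient
   additivity $r(N/X) + r(N/Y) = r(N)$ guarantees a side whose
   quotients are distinct with the reticulation precondition intact;
   recurse there (preference: a side where $N_1$'s quotient has
   strictly more reticulations, ties broken by smaller quotient, then
   lexicographically).
4. **n-cycle case.** If $N_2$ has no non-trivial split it is an
   $n$-cycle network. With $r(N_1)=1$ both networks carry exactly one
   cycle of length at least four and non-containment is the
   single-reticulation identifiability theorem from the prior
   literature; such certificates carry `external_theorem = TRUE` and are
   validated structurally, not by invariant evaluation. With
   $r(N_1)\ge 2$ the branch is unreachable (two distinct
   below-reticulation blocks cannot both be refined into one cycle);
   reaching it raises an internal error rather than guessing.

`distinguishable()` runs the search in both directions for equal
reticulation numbers, and `verify_certificate()` re-derives every link
of a certificate from scratch — restrictions recomputed, witnesses
re-established from the vanishing table, bookkeeping re-checked.

## Conventions and degenerate inputs

* **eNewick.** Hybrid vertices use `#H<k>` tags appearing exactly
  twice, with a subtree at exactly one occurrence. The parent edge of
  the *first* occurrence in reading order is `e1`, the edge kept with
  probability $\delta$. Serialization writes the subtree at the first
  traversal visit.
* **Canonical rooting.** A semi-directed network is rooted by
  subdividing the valid cut-edge nearest the lexicographically smallest
  taxon (a cut-edge is valid when it lies below no reticulation, the
  exact condition for a consistent orientation to exist). Root
  relocation invariance of the model — tested exactly on random
  networks — makes this choice immaterial.
* **Restriction collapse.** Restriction can shorten cycles: a 4-cycle
  may become a triangle (kept, and flagged by `validate_network()` —
  restrictions of triangle-free networks legitimately contain
  triangles, and the 4-leaf verdict machinery handles them); a cycle
  reduced to two parallel edges collapses, its reticulation absorbed
  into a convex matrix sum.
* **Ordering.** Taxa are processed in sorted label order; site patterns
  are enumerated lexicographically in base order A, G, C, T; set-valued
  outputs are sorted; block orders around cycles start at the
  reticulation and break the direction tie toward the smaller minimum
  taxon.

## The random network generator

`random_network(n, r, seed)` grows a random unrooted binary tree by
leaf insertion, then builds each reticulation cycle by replacing a
random path of $m$ unused internal vertices with a cycle of length
$m+2$ (so $m \ge 2$ keeps every cycle at length $\ge 4$), reattaching
the hanging edges in random cyclic order and choosing a random
reticulation vertex; constructions whose reticulation placements admit
no rooting are rejected and retried. It emulates the combinatorial
variety of the network class — cycle lengths, cycle nesting, block
sizes — and is deterministic given its seed. It is *not* a uniform
sampler over the class, and it generates topologies only, not
alignments with real-data features such as rate heterogeneity across
sites, indels or base-composition bias; passing tests therefore
establish the combinatorial and algebraic claims, not robustness of any
inference procedure on empirical alignments.

## Problem sizes and test design

The test suite establishes its claims at the following sizes, chosen so
that the full algebraic machinery is exercised end to end: the oracle
equivalence between the two parameterizations runs over the entire
57-network catalog with 50 exact-rational draws per constraint; the
verdict grid and every witness-set claim are recomputed from scratch
for JC, K2P and K3P; root-relocation invariance uses 50 random networks
of 5–7 taxa with exact draws (where dyadic exactness permits
`identical()` comparisons); and the two-sided certificate property runs
on 200 random pairs with up to 10 taxa and 3 reticulations, each
certificate re-verified independently. Properties at larger sizes
follow from the same induction and were spot-checked interactively.

## Known limitations

* Triangle-containing networks are handled as 4-leaf objects (they
  arise as restrictions) but the n-leaf distinguishability decision is
  only implemented for the triangle-free level-1 class, matching the
  scope of the underlying theory.
* Level-2 and higher networks, non-binary vertices, network inference
  from data, and computation of full vanishing ideals or their
  dimensions are out of scope.
* The single-cycle base case rests on an external theorem and is
  certified by citation, not by invariant evaluation.
* Generic identifiability is a statement about all parameters outside a
  measure-zero set; the package witnesses the variety-level geometry
  and does not attempt to quantify the exceptional set.

## A worked call

```{r example, eval = FALSE}
n1 <- random_network(8, r = 2, seed = 11)
n2 <- random_network(8, r = 2, seed = 12)
d <- distinguishable(n1, n2, "K2P")
glance(d)
tidy(d$cert_12)
verify_certificate(d$cert_12)
```
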