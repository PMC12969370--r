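---
title: "Graph-based matrix elements between genealogical CSFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based matrix elements between genealogical CSFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfgraph)
```

## The problem

Configuration state functions (CSFs) are spin-adapted many-electron basis
functions: unlike single Slater determinants they are eigenfunctions of the
total-spin operator $\hat S^2$, which removes spin contamination and makes
CI expansions more compact. The price is that matrix elements of
second-quantized operators are harder to evaluate than the Slater–Condon
rules for determinants, and many codes fall back on expanding every CSF into
determinants — an expansion that grows exponentially with the number of open
shells.

`csfgraph` computes $\langle \mathbf t', M' | \hat O | \mathbf t, M\rangle$
for an *arbitrary* ordered product of elementary creation/annihilation
operators $\hat O = \hat o_1 \hat o_2 \cdots \hat o_{N^{op}}$ between
genealogical CSFs without ever materializing the determinant expansion.  A
CSF over $n_o$ ordered orbitals is a step string $\mathbf t$ over `0`
(empty), `u` (singly occupied, raising the intermediate spin), `d` (singly
occupied, lowering it) and `2` (doubly occupied), plus a spin projection
$M$. Internally all spin bookkeeping uses the doubled integers $b_i = 2S_i$
and $x = 2M$.

## The graph picture

The determinant expansion of a CSF is encoded by a two-dimensional lattice
DAG: level $i$ of the graph corresponds to orbital $i$, the horizontal
coordinate $x$ of a node is the doubled spin projection accumulated so far,
and each root-to-end path is one determinant whose coefficient is the
product of the edge weights along the path. The weights are
Clebsch–Gordan-derived factors
$$C_{0,0}=1,\qquad C_{2,2}=(-1)^b,\qquad
  C_{u,\alpha}=\sqrt{\tfrac{b+x}{2b}},\qquad
  C_{u,\beta}=\sqrt{\tfrac{b-x}{2b}},$$
$$C_{d,\alpha}=(-1)^{b+1}\sqrt{\tfrac{b-x+2}{2(b+2)}},\qquad
  C_{d,\beta}=(-1)^{b}\sqrt{\tfrac{b+x+2}{2(b+2)}},$$
evaluated at the doubled spin $b_i$ of the target level and the coordinate
$x$ of the target node, with signs in the unitary-group-approach phase
convention. Because
$C_{u,\alpha}^2 + C_{u,\beta}^2 = C_{d,\alpha}^2 + C_{d,\beta}^2 = 1$
and
$C_{u,\alpha}(b{+}2,x)C_{d,\alpha}(b,x) + C_{u,\beta}(b{+}2,x)C_{d,\beta}(b,x)=0$,
CSFs are orthonormal, and both identities are asserted exactly in the test
suite for all $b \le 40$.

An elementary operator acting on orbital $i$ only changes the edges at level
$i$ and rigidly shifts all nodes above. The package therefore never stores
the graph: a (possibly modified) CSF is kept as the original data
$(\mathbf t, \mathbf b, \mathbf r, M)$ plus a vector $\mathbf q$ of modified
step values (now over $\{0,u,d,\alpha,\beta,2\}$), a vector $\boldsymbol\tau$
recording the original spin branch wherever an operator touched a singly
coupled level, the per-level coordinate shifts $\mathbf d$, and one global
phase $\phi \in \{-1, 0, +1\}$ that absorbs every fermionic sign
($\phi = 0$ is the annihilated state and propagates silently). The overlap
of two such states — and hence any matrix element, since
$\langle \mathbf t',M'|\hat O|\mathbf t,M\rangle$ is the overlap of the bra
graph with the operator-modified ket graph — is computed by sweeping a vector
of node values level by level through the overlaid graphs, updating only the
coordinates allowed by both states' recursive $x$-ranges. The cost is
quadratic in $n_o$, against the exponential growth of the determinant
expansion: for the ladder CSF $|u\cdots ud\cdots dd\rangle$ at $n = 20$ the
expansion has $\binom{20}{10} = 184756$ determinants while the graph has
$121$ nodes.

Matrix elements are screened first by necessary per-level selection rules
(`selection_rules()`): projection balance $2M' = 2M + 2M^{op}$, the triangle
bounds $|b_i - b_i'| \le N_i^{op}$ and $b_i + b_i' \ge |x_i^{op}|$, and the
parity condition $|b_i - b_i'| \equiv N_i^{op} \pmod 2$. For general
operator strings the total operator spin is not well defined, so only these
projection-based bounds apply; tighter bounds for spin-adapted operators are
deliberately out of scope. All vanishing elements are returned as zero
*values* with a machine-readable `reason` attribute, so screening statistics
can be collected.

## Exact arithmetic

Every edge weight is of the form $\pm\sqrt{p/q}$ with small rational $p/q$,
but the overlap sweep adds products of two such radicals, which is no longer
a single radical. Exact mode therefore works in the ring of finite sums
$\sum_s c_s \sqrt s$ with squarefree integer radicands $s$ and rational
coefficients $c_s$, which is closed under addition and multiplication.
Squarefree radicands are represented as bitmasks over the primes occurring
in the Clebsch–Gordan integers (so products and square extraction are mask
operations, and no large number is ever factored), and the coefficients are
exact rationals over arbitrary-precision integers implemented in C++ —
denominators are products over many levels and routinely exceed the exact
range of a double. Exact mode is the reference in every verification;
float mode is what a production caller would use and is validated against
the exact value. The float-mode early exit of the sweep ("all updated node
values are zero") tests for exact zeros only — no epsilon — so cancellation
noise can never silently truncate a sweep.

## Verification strategy

The package carries its own independent oracle (`oracle_matrix_element()`):
expand the ket into determinants, apply the operators determinant by
determinant with the standard ordered-spin-orbital fermionic signs, and
contract against the bra expansion. The graph engine and the oracle are
compared *exactly* (not to a tolerance) across:

* every bra/ket pair compatible in occupation pattern and spin projection,
  for every ket CSF at $n_o = 3..6$ with randomized 2- and 8-operator
  sequences — this candidate set is exhaustive for possibly nonzero
  elements, because two states whose occupation patterns differ share no
  determinant and are zero in both engines by construction (samples of such
  incompatible pairs are asserted zero as well);
* 1000 random triples at the (15 electrons, 15 orbitals, $S = 1/2$) setting,
  where float-mode deviations are additionally bounded by $10^{-12}$.

Physical invariants are recovered exactly from elementary-operator strings:
$\langle \hat S^2\rangle = S(S+1)$ assembled as
$\hat S_-\hat S_+ + \hat S_z(\hat S_z + 1)$, $\langle \hat S_z\rangle = M$,
$\langle \hat N\rangle = N$, the anticommutation relations
$\{\hat a_{i\sigma}, \hat a_{j\sigma'}^\dagger\} = \delta_{ij}
\delta_{\sigma\sigma'}$ element-wise, and adjoint symmetry under reversing
the operator string and flipping daggers.

One transition-table subtlety deserves a note. The per-level update rules
for $(\mathbf q, \boldsymbol\tau, \phi, \mathbf d)$ are fixed by the
per-edge effects of each elementary operator together with the $\tau$
bookkeeping; the package validates them against the fully worked
two-operator reference state (both intermediate and final $\mathbf q$,
$\boldsymbol\tau$, $\mathbf d$, $\phi$, and the $x$-range vectors) in
`test-gdg-engine.R`, and that validation is intentionally kept as a
regression test. For the edge-weight table the recorded branch label
$\tilde\tau_i$ (i.e. $\tau_i$, falling back to $t_i$ when no operator
touched the level) is applied uniformly to *all* single-edge rows including
$q_i \in \{\alpha, \beta\}$: $C_{t,\tau}$ is undefined for $\tau = 0$ with
$t \in \{0, 2\}$, and the uniform rule reproduces unchanged weights for
edges surviving from empty or doubly occupied levels, which is what the
per-edge operator rules require. Likewise, the $x$ in the weight tables is
read as the *target-node* coordinate, so $x - d_i$ recovers the original
coordinate of a shifted node; this is the only reading consistent with the
node-value update table and with the determinant oracle (the overlap sweep
and the oracle agree exactly under it, and would not under the origin-node
reading).

## The synthetic benchmark generator

`run_benchmark()` reproduces the numerical experiment at desk scale. For a
fixed $(N, n_o, S, M)$ it samples ket CSFs uniformly (dynamic programming
over step-vector completion counts), builds an operator sequence of $N^{op}$
elementary operators — half creation, half annihilation, constructed
rightmost-first so that each annihilation targets a currently occupied
orbital and each creation a not doubly occupied one, with uniform spins —
and samples a bra uniformly among the CSFs passing the occupation and spin
selection rules against the modified ket. The exact-mode graph value is the
reference; both engines' float results are accumulated into RMS and maximum
absolute errors, total times, and the total determinant count of the ket
expansions. Randomness comes from R's Mersenne-Twister stream, so one seed
reproduces a whole run; sequences that annihilate the ket are kept and
counted (the zero fraction is reported) rather than discarded.

What the generator emulates is the shape of the published experiment:
uniform CSFs at fixed particle number and spin, short physical operator
strings (2 operators for one-particle, 8 for four-particle density-matrix
work), and bras restricted to the coupled candidate set. What it does not
emulate is anything about real molecular Hamiltonians — no integrals, no
locality structure, no sparsity pattern of an actual CI space — so passing
benchmarks demonstrate numerical correctness and scaling behaviour of the
matrix-element engine, not chemical accuracy of any application. Shipped
test configurations are scaled down (hundreds to thousands of elements at
$n_o \le 15$) so the whole suite runs in minutes; the samplers accept any
feasible $(N, n_o, 2S, 2M, N^{op})$ if a larger profile is wanted, e.g.
`bench_config(20, 20, 0, 0, N_op = 8, n_coup = 1e5)` from the command-line
runner.

```{r bench}
res <- run_benchmark(bench_config(10, 10, S2 = 0, N_op = 2, n_coup = 50,
                                  seed = 42))
res
```

## Numerical choices and degenerate inputs

* Zero-weight edges (e.g. $C_{u,\alpha}(b, -b) = 0$) are dropped from
  expansions and graphs; on paths inside the spin boundary they cannot
  occur, so the expansion size equals the lattice-path count.
* The node-value vector is bounded to $x \in [-n_o, n_o]$ (plus one guard
  slot per side); coordinates outside the intersected ranges are exact
  zeros.
* The determinant oracle refuses CSFs with more than 20 singly occupied
  orbitals — the expansion would be too large for the deliberately naive
  algorithm — and reports the refusal; the graph engine has no such limit.
* Timings in benchmark reports are wall-clock and hardware dependent; they
  are reported but never asserted.
* The empty operator string is the identity: the matrix element reduces to
  the CSF overlap (1 for identical, 0 for distinct CSFs, both exact).
* `sample_coupled_csf()` raises an error when no CSF can couple (the
  benchmark then resamples the sequence); `run_benchmark()` bounds the
  retries.

## Known limitations

Only single bra/ket CSFs are handled — no linear combinations as
wave-function objects, no sigma vectors, no transformation of CSF sets to a
common determinant basis, and no closed-form couplings for spin-adapted
(singlet) excitation operators; callers compose any spin-free operator from
elementary ones, as the $\hat S^2$ recovery test does. Only the
genealogical coupling scheme is supported (no Rumer or Serber bases). The
exact-arithmetic layer handles signed square roots of rationals and their
finite sums — exactly the closure of the quantities this algorithm
produces — not general algebraic numbers.
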