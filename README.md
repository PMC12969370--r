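# csfgraph

Matrix elements of arbitrary second-quantized operator sequences between
spin-adapted configuration state functions (CSFs), computed on a compact
graph representation — never through an explicit Slater-determinant
expansion.

## Who this is for, and what it does

CSFs built in the genealogical coupling scheme are eigenfunctions of the
total spin Ŝ², which makes them the natural basis for spin-pure
configuration-interaction methods, but evaluating
⟨**t**′, *M*′ | Ô | **t**, *M*⟩ for a general operator string
Ô = ô₁ô₂···ô_Nop is the classic obstacle: the determinant expansion of a CSF
grows exponentially with the number of open shells. `csfgraph` encodes the
expansion as a two-dimensional lattice graph whose root-to-end paths are the
determinants, with path-product weights given by Clebsch–Gordan-derived
factors (in the unitary-group phase convention):

    C00 = 1                      C22 = (−1)^b
    Cuα = √((b+x)/2b)            Cuβ = √((b−x)/2b)
    Cdα = (−1)^(b+1) √((b−x+2)/(2b+4))
    Cdβ = (−1)^b √((b+x+2)/(2b+4))

where b = 2S and x = 2M are doubled intermediate spins and projections.
Elementary creation/annihilation operators act directly on a compact state
(modified step values **q**, original spin branches **τ**, coordinate shifts
**d**, global phase ϕ), and the matrix element is the overlap of the bra
graph with the operator-modified ket graph, computed by one level-by-level
sweep of node values. Cost grows quadratically with the orbital count where
the determinant expansion grows exponentially: at n = 20 the ladder CSF
|uu···ud···dd⟩ expands to binom(20,10) = 184756 determinants, while its
graph has 121 nodes.

Everything can be computed either in floating point or *exactly*, in the
ring of finite sums of signed square roots of rationals (arbitrary-precision
rational coefficients, squarefree radicands), so every verification in the
package asserts identity, not closeness. An independent determinant-
expansion oracle and a seeded dual-engine benchmark harness are included.

## Worked example

```r
library(csfgraph)

ket <- parse_csf("uud0uu2d", 1)   # 8 orbitals, N = 8 electrons, S = 1, M = 1
ket$b   # doubled intermediate spins: 1 2 1 1 2 3 3 2
ket$r   # cumulative open shells:     1 2 3 3 4 5 5 6

# a two-orbital CSF and its full expansion, exact coefficients included
expand_csf(parse_csf("ud", 0), exact = TRUE)
#>   det coefficient coefficient_exact
#> 1  ba  -0.7071068        -sqrt(1/2)
#> 2  ab   0.7071068         sqrt(1/2)

# coefficient of one determinant in the ket's expansion
det_coefficient(ket, "aba0ab2a")                        # 0.1178511
format(det_coefficient(ket, "aba0ab2a", exact = TRUE))  # "sqrt(1/72)"

# apply the operator string  a†(1,β) a(7,β)  -- tokens are written order,
# rightmost applied first -- and inspect the compact graph state
s <- apply_sequence(init_state(ket), "1b+ 7b-")
s
#> <gdg_state> over |uud0uu2d, M = 1>
#>   q   = (2,u,d,0,u,u,a,d)
#>   tau = (a,0,0,0,0,0,0,0)
#>   d   = (-1,-1,-1,-1,-1,-1,0,0)
#>   phi = -1

# the matrix element against a coupled bra CSF, exactly and in float
bra <- parse_csf("2ud0uuud", 1)
matrix_element(bra, "1b+ 7b-", ket, exact = TRUE)
#> <radsum> -sqrt(121/192)  (-0.793856620135735)
oracle_matrix_element(bra, "1b+ 7b-", ket)   # -0.7938566 (independent engine)
```

The negative square root of 121/192 is the exact coupling between the two
CSFs; the explicit determinant engine reproduces it to machine precision.

A seeded benchmark comparing both engines against the exact reference:

```r
run_benchmark(bench_config(10, 10, S2 = 0, N_op = 2, n_coup = 50, seed = 42))
#> benchmark: N=10 n_o=10 2S=0 2M=0 N_op=2 n_coup=50
#>        engine n_eval         rmsd      max_abs time_s n_det
#>         graph     50 9.945640e-17 2.220446e-16  0.042   396
#>  determinants     50 1.000934e-16 2.220446e-16  0.036   396
#> zero elements: 2.0%; oracle skipped: 0
```

Command-line wrappers live under `inst/cli/`:

```sh
Rscript inst/cli/matel.R --bra 2ud0uuud --bra-M 1 --ket uud0uu2d --ket-M 1 \
        --op "1b+ 7b-" --exact
Rscript inst/cli/bench.R --electrons 15 --orbitals 15 --spin2 1 --ncoup 1000 --seed 1
```

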