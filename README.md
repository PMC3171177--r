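# ppdsinfer

Reverse engineering of gene regulatory networks as **probabilistic
polynomial dynamical systems** (PPDS) over prime finite fields.

## The problem

Discretized gene-expression time courses — each gene at one of *p* levels
(Boolean, ternary, ...) — are short, noisy, and cover a vanishing fraction
of the 2^n (or p^n) possible network states. Any method that returns a
single deterministic dynamic model is silently choosing among the many
models that fit the data equally well. `ppdsinfer` instead returns *all*
minimal fitting models, each with a probability reflecting how much of the
space of model-selection choices leads to it, assembled into one stochastic
dynamical system whose behavior and dependency structure can then be
analysed directly.

## The method

Over the field F_p every update rule is a polynomial, so a synchronous
network model is a polynomial dynamical system F = (f_1, ..., f_n) :
F_p^n -> F_p^n. Given observed transitions with input states V:

1. all polynomials fitting node *i* differ by the **ideal of points**
   I(V) = { h : h(s) = 0 for all s in V };
2. for a monomial ordering (encoded by a weight vector w with a fixed
   lexicographic tiebreak), reducing an interpolant modulo the reduced
   Gröbner basis of I(V) — computed by the Buchberger–Möller algorithm —
   yields the unique **minimal model**: no term of it vanishes identically
   on the data;
3. weight space is partitioned into the cones of the **Gröbner fan** of
   I(V), one per marked reduced Gröbner basis; sampling weight vectors
   uniformly from an integer box and mapping each to its minimal model
   estimates the relative cone volumes;
4. the sampled models are merged per node: distinct coordinate polynomials
   become the node's options, with probabilities equal to their summed cone
   volumes (exact rational counts). One option per node is drawn
   independently at each synchronous update step.

The option probabilities also weight the **dependency graph**
(W[i,j] = summed probability of x_i's options involving x_j), which can be
scored against a reference wiring by probability-weighted PPV, sensitivity
and specificity. Exact stochastic **state spaces**, fixed points with exact
and Monte-Carlo **stabilities**, weakly connected components, and
trajectory simulation complete the analysis toolkit.

## Worked example

A bundled 3-gene ternary time course of four consecutive states:

```r
library(ppdsinfer)
series <- system.file("extdata", "ternary3_series.tsv", package = "ppdsinfer")
data  <- read_transitions(series, "series", p = 3)
model <- infer(data, s = 2000, B = 100, seed = 1)
model
#> PPDS over GF(3), 3 nodes
#>   f_1 (x1):
#>     x2 + 2*x3   [1020/2000 = 0.510]
#>     2*x1 + 2*x3   [980/2000 = 0.490]
#>   f_2 (x2):
#>     2*x2 + x3   [1020/2000 = 0.510]
#>     x1 + x3   [980/2000 = 0.490]
#>   f_3 (x3):
#>     x2 + x3 + 2   [1020/2000 = 0.510]
#>     2*x1 + x3 + 2   [980/2000 = 0.490]
```

Exactly two minimal models fit these data — one driven by x2, one by x1 —
and the sampled fan splits between their two cones almost evenly (1020 vs
980 of 2000 draws; the true cone volumes are equal). Every option involves
x3, so x3's influence is certain, while the data cannot distinguish x1
from x2:

```r
round(dependency_graph(model), 2)
#>      x1   x2 x3
#> x1 0.49 0.51  1
#> x2 0.49 0.51  1
#> x3 0.49 0.51  1

fixed_points(model)
#>   state index stability absorbing
#> 1 0,1,1     5  0.127449     FALSE
#> 2 1,1,0    13  0.127449     FALSE
#> 3 2,0,1    20  0.122451     FALSE
#> 4 2,1,2    24  1.000000      TRUE
#> 5 2,2,0    25  0.122451     FALSE

length(state_components(build_state_space(model)))
#> [1] 1
```

The stochastic state space on all 27 states forms a single weakly
connected component with five steady states; (2,1,2) is fixed by both
minimal models, hence absorbing (stability 1), while the other four are
fixed only under one option combination each (stability about 1/8).

A larger bundled example — 54 Boolean transitions of the 11-regulator
yeast cell-cycle network (a documented synthetic stand-in, see
`inst/extdata/README.md`) — is analysed end-to-end in the test suite,
including `representative_pds()`, which reduces a PPDS to its per-node
most-probable option for basin/steady-state summaries when the model space
is large.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ppds.R", package="ppdsinfer"))')" \
  infer --data series.tsv --format series --field 3 --seed 1 --out model.json
# further subcommands: dynamics, score, simulate, generate, discretize
```

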