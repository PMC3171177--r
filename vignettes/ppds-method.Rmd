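---
title: "Reverse engineering regulatory networks as probabilistic polynomial dynamical systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse engineering regulatory networks as probabilistic polynomial dynamical systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdsinfer)
```

## The model

Discretized expression data assign each of $n$ regulators a level in
$\{0, \dots, p-1\}$ for a prime $p$ (Boolean data: $p = 2$; ternary:
$p = 3$). Endowing the level set with the arithmetic of the finite field
$\mathbb{F}_p$ makes *every* update rule a polynomial: any function
$\mathbb{F}_p^n \to \mathbb{F}_p$ is polynomial, so a synchronous dynamic
model of the network is a **polynomial dynamical system** (PDS)
$F = (f_1, \dots, f_n) : \mathbb{F}_p^n \to \mathbb{F}_p^n$. This is not a
modelling assumption but a representation theorem; Boolean networks are the
$p = 2$ case.

Short time courses never determine $F$. If $f_i$ and $g_i$ both reproduce
the observed successor values of node $i$ on the observed input states
$V = \{\mathbf{s}_1, \dots, \mathbf{s}_m\}$, their difference vanishes on
$V$, i.e. lies in the **ideal of points**
$I(V) = \{h : h(\mathbf{s}) = 0 \ \forall \mathbf{s} \in V\}$. The whole
model space of node $i$ is therefore one interpolant plus $I(V)$, and a
canonical *minimal* representative is obtained by reducing an interpolant to
its normal form modulo a Gröbner basis of $I(V)$: the result contains no
term that vanishes identically on the data, and is supported on the
*standard monomials*, of which there is exactly one per data point.

The minimal model depends on the **monomial ordering** used for the Gröbner
basis. We encode orderings by a nonnegative integer weight vector $\omega$
with a fixed lexicographic tiebreak ($x_1 \succ \dots \succ x_n$):
$x^\alpha \succ_{\omega} x^\beta$ iff $\omega\cdot\alpha >
\omega\cdot\beta$, ties resolved lexicographically. Weight space decomposes
into the polyhedral cones of the **Gröbner fan** of $I(V)$; all orderings in
one cone give the same marked reduced Gröbner basis, hence the same minimal
model. Instead of privileging one ordering, the method samples weight
vectors uniformly, maps each to its minimal model, and assembles a
**probabilistic PDS** (PPDS): per node, the list of distinct coordinate
polynomials encountered, each weighted by the relative frequency of its
cone, i.e. an estimate of relative cone volume. At simulation time one
option per node is drawn independently at each synchronous step.

The probability weights double as **dependency strengths**: the strength of
the dependency of $x_i$ on $x_j$ is the summed probability of $x_i$'s
options whose canonical form involves $x_j$. A strength of 1 means no
fitting minimal model can avoid $x_j$ when updating $x_i$.

## Algorithmic choices

**Gröbner bases of ideals of points.** The production route is the
Buchberger–Möller algorithm: candidate monomials are visited in increasing
$\succ_\omega$-order; a candidate whose evaluation vector on $V$ depends
linearly on those of the standard monomials found so far contributes a
(reduced, monic) basis element, an independent one becomes a standard
monomial. This is exact over $\mathbb{F}_p$ and runs in time polynomial in
$m$ and $n$. A classical Buchberger implementation (S-polynomials plus
inter-reduction, with the field equations $x_i^p - x_i$ added to the
generators) is retained purely as an independent cross-check; the test
suite verifies both routes produce identical marked reduced bases on small
ideals.

**Minimal models.** Two equivalent routes are implemented and tested
against each other: normal-form reduction of an indicator-polynomial
interpolant, and a direct linear solve for the unique fitting polynomial
supported on the standard monomials. The solver route is the default: it
avoids building the (dense) interpolant, which for Boolean data has up to
$2^n$ terms per observed state.

**Canonical forms.** All reported polynomials are reduced modulo the field
equations (every exponent at most $p-1$), with terms sorted under a fixed
reference order, so equality of models is literal equality of
representations. Probabilities are kept as exact integer counts over the
common sample total, so per-node probabilities sum to exactly 1; merging
options never loses mass to rounding.

**Division tie-breaks.** When several basis elements could reduce a leading
term, the divisor whose initial term is smallest in the active ordering is
used. For a Gröbner basis the remainder is unique regardless, so this
choice only affects intermediate work.

## Tunable parameters

* `s` — number of sampled orderings. The default derives from a normal
  approximation for a proportion at worst case $1/2$:
  $s \ge z^2_{(1+c)/2}\, 0.25 / m^2$ with margin $m = 0.05$ and confidence
  $c = 0.95$ gives $s = 385$; cone-volume estimates are then accurate to
  about $\pm 0.05$. The worked analyses in the tests and the acceptance
  script use $s = 2000$ for the three-gene example (margin
  $\approx 0.022$) and $s = 385$ for the 11-regulator data.
* `B` — the sampling box bound: weight vectors are drawn i.i.d. uniform on
  $\{0, \dots, B\}^n$, default $B = 100$. Cones are scale-invariant, so
  box-uniform hit frequencies approximate relative cone volumes; $B$ only
  controls how finely near-degenerate cones around the box boundary are
  resolved. Entries may be 0 — the lexicographic tiebreak keeps the
  ordering total. On the bundled examples the distinct-model set is
  identical for $B$ from 1 to 100.
* `mode = "saturate"` — keeps sampling until no new distinct model has
  appeared for `saturation_window` (default 500) consecutive draws, up to a
  hard cap; used when the goal is the complete distinct-model list of a
  small instance rather than volume estimates.
* `noise_rate` in the synthetic generator — per-coordinate probability of
  replacing a recorded level by a uniformly chosen different level.

## The synthetic-data generator

`generate_synthetic()` iterates a known (possibly probabilistic) polynomial
system from chosen start states and records consecutive pairs, optionally
corrupted by state-flip noise. It emulates the *structure* of discretized
time-course data — short trajectories, partial state-space coverage,
observation noise — but not the upstream reality of expression profiling:
continuous kinetics, unequal sampling intervals, discretization artifacts,
or correlated (non-independent) measurement error. Recovery results on
synthetic data therefore certify the inference machinery (e.g. exhaustive
noiseless data provably pins down the generating model, and the tests
confirm the pipeline returns it with probability 1 per node), not
performance on microarray pipelines.

The bundled 11-regulator Boolean data set is likewise synthetic: 54
consistent transitions (4 steady) generated once from the standard
cell-cycle Boolean threshold network by a fixed trajectory-selection
protocol, documented in `inst/extdata/README.md`. The published table it
stands in for is not available in a consistent form.

## Reading dynamics off the inferred model

`build_state_space()` enumerates all $p^n$ states with exact edge
probabilities (product over nodes of the option mass yielding each
coordinate). *Fixed points* are states with positive self-transition
probability; their *stability* is that probability, reported exactly and,
optionally, as a seeded Monte-Carlo estimate (one synchronous update per
run). *Components* are weakly connected components of the transition graph
— the direction-blind reading is the one under which a 27-state example
space with five fixed points forms a single component, matching how such
spaces are described in practice.

Two empirical regimes matter. On very small model spaces (the three-gene
ternary example: two cones of equal volume) the stochastic state space is
informative as is. On realistic data sizes the Gröbner fan fragments: for
the bundled 54-transition Boolean data essentially every sampled ordering
yields a distinct minimal model, per-node option lists grow into the tens,
and the union state space collapses into one densely connected component.
For that regime `representative_pds()` reduces the PPDS to its per-node
most-probable option; the resulting functional graph decomposes into
basins, each ending in exactly one steady state, which is the natural
summary for comparing attractor structure against a reference model (the
acceptance suite checks exactly this structural property and the recovery
of all four observed steady states).

## Numerical and degenerate-input conventions

* Only prime fields are supported; the field order is validated.
* Data must describe a function: two pairs with equal input and different
  output raise an error naming the conflicting state. An opt-in majority
  vote resolves conflicts for noisy data; identical duplicate pairs are
  dropped silently. Consecutive series (blank-line separated) are chained
  into pairs.
* The empty basis is a legal divisor list (normal form then only reduces
  exponents); the empty point set is rejected (its ideal is the whole
  ring).
* Constant columns discretize to level 0 with a warning; discretization is
  rank-based, hence invariant under monotone transforms, with level counts
  balanced to within one.
* All randomness (weight sampling, simulation, noise) flows through a
  single integer seed per entry point.

## Known limitations

* Exact polyhedral Gröbner-fan computation is out of scope; cone volumes
  are sampling estimates with the stated margin, and rare cones (volume
  $\ll 1/s$) can be missed — `mode = "saturate"` mitigates but cannot
  guarantee completeness.
* The state-space builder enumerates $p^n$ states (capped at $2^{20}$ by
  default); larger systems must be explored by simulation.
* Minimality is per-coordinate and ordering-relative, as defined by
  normal-form reduction; it does not minimize biological parsimony
  criteria such as canalyzing depth.
* Dependency scoring compares variable *presence*; it does not orient
  activation versus inhibition.

## A worked run

```{r example}
series <- system.file("extdata", "ternary3_series.tsv", package = "ppdsinfer")
data <- read_transitions(series, "series", p = 3)
model <- infer(data, s = 2000, B = 100, seed = 1)
model

fixed_points(model)
length(state_components(build_state_space(model)))
round(dependency_graph(model), 2)
```

The two minimal models split the fan evenly; every option for $x_1$
involves $x_3$ (strength 1) while $x_1$ and $x_2$ each appear in half of
the fan (strength about 0.5), and the 27-state space is one weak component
with five fixed points.
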