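# moranfix

Exact and Monte Carlo fixation probabilities for the Moran birth–death
process on undirected graphs — a toolkit for evolutionary graph theory,
built around the question: *which population structures amplify, and which
suppress, the advantage of a fitter invader?*

## The problem

Place a single mutant of relative fitness *r* (residents have fitness 1) on
a vertex of a connected undirected graph *G* with *N* vertices. At each step
an individual reproduces with probability proportional to its fitness and
its offspring replaces a uniformly chosen neighbor (`w_ij = 1/d_i`). The
invader lineage eventually either dies out or takes over the graph; the
probability of takeover, averaged over a uniformly random starting vertex,
is the **average fixation probability** Φ(*r*).

For a well-mixed population (complete graph) the classical closed form is

    Φ0(r) = r^(N-1) (r - 1) / (r^N - 1),        Φ0(1) = 1/N.

By the Circulation Theorem every *isothermal* graph (constant vertex
temperature `T_i = Σ_{j~i} 1/d_j`) has Φ = Φ0. A graph is an **amplifier of
selection** if Φ(*r*) > Φ0(*r*) for all *r* > 1 and a **suppressor** if
Φ(*r*) < Φ0(*r*) for all *r* > 1 (inequalities reverse for *r* < 1). Stars
and complete bipartite graphs amplify; undirected suppressors are rare, and
certifying one requires *strict* inequalities for *every* r > 1 — which
floating point cannot deliver. moranfix therefore works over
arbitrary-precision rationals (GMP) end to end:

* **Full-state solve** — the absorbing chain on all 2^N invader sets,
  eliminated level by level (the chain only moves between adjacent
  invader-count levels, so the system is block tridiagonal).
* **Symmetry lumping** — for the *ell-graph* family (a clique K_2n split
  into halves A and B, plus extra vertices u–A, v–B, u–v) the automorphism
  group reduces the 2^N states to N(N+1)/2 orbits (e, k, k′, e′):
  21, 36, 55 states for orders 6, 8, 10.
* **Rational-function reconstruction** — Φ(*r*) is a quotient of
  polynomials of degree ≤ d = N(N+1)/2 − 2; evaluating the lumped chain at
  the 2d low-complexity nodes {1..d+1, 1/2..1/d} and solving the linear
  system recovers Φ exactly, with held-out nodes validating the result.
* **Sturm certification** — the sign of Δ(r) = Φ(r) − Φ0(r) is certified on
  the whole intervals (1, ∞) and (0, 1) by exact real-root isolation, which
  is how the ell-graphs of orders 6, 8 and 10 are *proved* to be
  suppressors rather than sampled.
* **Embedded-chain Monte Carlo** — for larger graphs, stochastic estimates
  that sample only state-changing replacement events, with Wilson 99%
  confidence intervals.
* **Exhaustive scans** — every connected graph of order ≤ 7 up to
  isomorphism, classified on an exact fitness grid.

## Worked example

```r
library(moranfix)

g <- make_ell_graph(2)        # the order-6 ell-graph
g
#> moran_graph: 6 vertices (0..5), 11 edges
#> degree sequence: 4 4 4 4 3 3

# exact fixation probability at fitness r = 2, via the 21-orbit lumped chain
phi <- reduced_fixation(2, 2)
rat_num(phi)                              # 0.5070764
phi0_exact(2, 6)                          # "32/63" = 0.5079365
rat_num(rat_arith(phi, phi0_exact(2, 6), "-"))
#> -0.0008601199                           # below the well-mixed baseline

# certify the suppressor property for ALL r > 1, not just a sample
f <- reconstruct_ell_phi(2)   # exact rational function Phi(r), held-out validated
classify(f)
#> verdict: suppressor  [symbolic mode]
#>   Sturm: Delta'' always+ on (0,Inf); (r-1)^1 removed from Delta';
#>   Delta always- on (1,Inf), always+ on (0,1)

# Monte Carlo cross-check
estimate_fixation(g, 2, trials = 1e5, seed = 1)
#> MC fixation estimate: 0.50612  (50612/100000 trials, 99% CI [0.502047, 0.510192])
```

The exact value of Φ at r = 2 is the rational
`290563457033894472128/573017130923792511951` ≈ 0.5070764: about 0.09
percentage points below Φ0(2) = 32/63. The deviation is small — which is
precisely why exact arithmetic, and not simulation alone, is needed to
certify its sign everywhere.

A command-line interface wraps the same machinery:

```sh
moranfix exact --graph ell:2 --r 2
moranfix scan --order 6 --out scan6.csv
moranfix mc-curve --graph ell:5 --rmin 0 --rmax 4 --rstep 0.25 --trials 1000000 --seed 7
```

## Package layout

| | |
|---|---|
| `R/graphs.R` | graph construction, temperatures, enumeration, edge-list IO |
| `R/exact.R` | full-state exact solver |
| `R/lumped.R` | orbit states and the lumped chain |
| `R/rational-function.R` | Φ0, reconstruction, Sturm certification, classification |
| `R/montecarlo.R` | embedded-chain simulation |
| `R/cli.R` | graph specs, exhaustive scans, config runner, CLI dispatcher |
| `src/` | GMP-backed exact kernels (Rcpp) |
| `vignettes/` | methods vignette: model, algorithms, design choices |
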