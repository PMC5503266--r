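---
title: "Exact certification of suppressors and amplifiers of selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact certification of suppressors and amplifiers of selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranfix)
```

## The model

moranfix implements the Moran process with birth–death updating on a
connected undirected graph $G$ with vertex set $\{0, \dots, N-1\}$. A state
is the set $S$ of vertices occupied by invaders. One step: an individual is
chosen to reproduce with probability proportional to its fitness ($r > 0$
for invaders, $1$ for residents), and its offspring replaces a uniformly
random neighbor, so the replacement weight is $w_{ij} = 1/d_i$ for $i \sim
j$. The one-step probability of gaining vertex $j$ is
$r \sum_{i \in S} w_{ij} / w_S$ and of losing vertex $j$ is
$\sum_{i \notin S} w_{ij} / w_S$, with total reproductive weight
$w_S = r|S| + N - |S|$; all remaining mass is a self-loop. On a connected
undirected graph the only recurrent states are $\emptyset$ (extinction) and
$V$ (fixation), so the fixation probabilities $\Phi_S$ solve the absorbing
linear system uniquely. The *average* fixation probability $\Phi(r)$ is the
mean of $\Phi_{\{i\}}$ over a uniformly random single-invader start.

Assumptions worth keeping in mind: constant (frequency-independent)
fitness, no mutation during the sweep, undirected simple graphs only, and
birth–death order of events. Death–birth updating, directed graphs and
weighted replacement other than $1/d_i$ are out of scope.

The central comparison object is the well-mixed baseline
$\Phi_0(r) = r^{N-1}(r-1)/(r^N - 1)$ (continuity value $1/N$ at $r = 1$).
A graph *amplifies* selection when $\Phi(r) > \Phi_0(r)$ for all $r > 1$
and *suppresses* it when $\Phi(r) < \Phi_0(r)$ for all $r > 1$; both
definitions quantify over an entire open interval, which drives every
design decision below: the deviations involved can be of order $10^{-3}$
and the claims are strict inequalities, so the package computes over
arbitrary-precision rationals (GMP) wherever a verdict depends on a sign.

## Exact solver

`fixation_vector()` solves the $2^N$-state chain. Two structural facts keep
this cheap enough up to $N = 14$ (the default refusal threshold — above it
the dense level blocks, up to $\binom{N}{N/2}$ states wide, dominate both
memory and time):

* Only the *embedded* chain matters for absorption: self-loop mass is
  dropped and only state-changing rates are assembled, which also removes
  $w_S$ from the computation entirely.
* Transitions only connect invader-count levels $k$ and $k \pm 1$, so in
  level order the transient system is block tridiagonal with blocks of
  width $\binom{N}{k}$. With $\Phi = 0$ on the bottom level, forward
  elimination gives $\Phi_k = U_k \Phi_{k+1}$, and the top level closes the
  recursion with $\Phi_V = 1$. Each level requires one exact dense solve;
  pivots are chosen as the nonzero entry of smallest bit size, which in
  practice keeps intermediate rationals compact.

This replaces a generic sparse Gaussian elimination over the full $2^N$
system: the solutions are identical (same linear system, reordered), but
the level structure bounds fill-in a priori.

## Symmetry lumping for ell-graphs

The ell-graph of order $N = 2n+2$ is $K_{2n}$ with its vertex set split
into halves $A$ ($0..n-1$) and $B$ ($n..2n-1$), plus extra vertices $u$
(adjacent to $A$ and $v$) and $v$ (adjacent to $B$ and $u$). Its
automorphisms — permutations within each half, and the swap
$(A,u) \leftrightarrow (B,v)$ — induce the orbit label
$(e, k, k', e')$: occupancy of $u$, invader counts in $A$ and $B$,
occupancy of $v$. Because the partition is automorphism-induced, the chain
is strongly lumpable: the summed rate from any representative of one orbit
to all members of another does not depend on the representative, and the
lumped chain has exactly the same fixation probabilities. The canonical
orbit count is $N(N+1)/2$ — 21, 36, 55 for orders 6, 8, 10 — versus $2^N$.

Two design points:

* **Canonical representative.** The swap identifies $(e,k,k',e')$ with
  $(e',k',k,e)$. When $k \ne k'$ *and* $e \ne e'$ point in opposite
  directions, any tie-break is consistent; we canonicalize by
  $(k, e) \ge_{\mathrm{lex}} (k', e')$. The choice is pure bookkeeping — it
  relabels orbits but cannot change the lumped dynamics, which the suite
  verifies by exact equality against the full $2^N$ solve.
* **Unbalanced variants.** The same construction with part sizes
  $p \ne q$ loses the swap symmetry but keeps $S_p \times S_q$; the lumped
  state space is then all $4(p+1)(q+1)$ tuples. This generalization is what
  lets small unbalanced variants be checked exactly against full solves.

Lumped rates are computed from one explicit representative per orbit
(first $k$ vertices of $A$, etc.) in $O(N)$ per row — never by enumerating
$2^N$ states — so exact solves remain instant up to $n = 11$ (order 24).

## Reconstructing $\Phi$ as an exact rational function

$\Phi(r)$ is a quotient of polynomials in $r$ with rational coefficients;
for ell-graphs the degree is bounded by $d = N(N+1)/2 - 2$, and since
$\Phi \to 1$ as $r \to \infty$ both leading coefficients can be normalized
to 1, leaving $2d$ unknowns. Evaluating the lumped chain at the $2d$ nodes
$\{1, \dots, d+1, 1/2, \dots, 1/d\}$ — the lowest-complexity rationals,
which empirically keeps coefficient bit-lengths manageable — yields a
square linear system solved exactly.

* **Degree degeneracy.** If the true degree $d^*$ is below $d$, degree-$d$
  representations form an affine family and the system is singular. The
  rank defect of the $2d \times 2d$ matrix equals $d - d^*$, so one
  elimination diagnoses the right degree and a single retry at $d^*$
  suffices (the observed degrees for orders 6, 8, 10 are 17, 31, 49
  against nominal bounds 19, 34, 53).
* **Held-out certification.** `reconstruct_ell_phi()` evaluates three
  extra nodes ($d+2, d+3, d+4$) that never enter the linear system; any
  mismatch there is a hard error. A returned function therefore reproduces
  every computed evaluation exactly, which is the package's defense against
  both software bugs and a wrong degree bound.

## Sign certification

`delta_function()` forms $\Delta = \Phi - \Phi_0$ over the common
denominator $(r^N - 1)\,\Phi''(r)$ and reduces by the polynomial GCD —
this cancels the removable singularity both parts share at $r = 1$ and any
spurious common roots that would confuse root counting. Coefficients are
normalized to primitive integer vectors (a positive scaling, so signs are
untouched).

`certify_sign()` then decides the sign of a polynomial on an open interval
by Sturm sequences over exact rationals: square-free part first, then the
standard remainder sequence with primitive-part normalization at each step
to control coefficient growth (at order 10 the certified numerator has
degree 58). Two endpoint subtleties: roots exactly at an endpoint are
divided out (they are not in the open interval), and when the divided-out
factor $(x-b)^m$ has odd multiplicity the reported sign on $(a, b)$ is
flipped accordingly. For the suppressor verdict the denominator is first
certified `always+` on $(0, \infty)$; the forced root of the numerator at
$r = 1$ (where $\Delta(1) = 0$) is removed; and the verdict requires
`always-` on $(1, \infty)$ together with `always+` on $(0, 1)$.

Grid mode (`classify()` on a graph, used by `scan_order()`) mirrors the
same definition restricted to a finite grid — the conventional
operationalization for exhaustive scans, with the default grid
$0.25, 0.5, \dots, 10$. All grid values are exact quarters and all
comparisons exact, because isothermal graphs sit exactly on $\Delta = 0$
and would be misclassified by floating-point ties. A grid verdict is
necessarily weaker than the symbolic one: it certifies signs at 40 points,
not on the continuum.

## Enumeration of small graphs

`enumerate_connected_graphs()` scans all $2^{N(N-1)/2}$ labeled graphs,
keeps the connected ones, and deduplicates by a canonical key: the minimal
upper-triangle adjacency bit-string over vertex orderings compatible with
iterated-degree (Weisfeiler–Leman style) invariant classes. The classes
are isomorphism invariants, so this induces the same equivalence as the
defining minimum over all $N!$ orderings while staying tractable at
$N = 7$ (853 classes); the $N!$ brute force is retained as the test oracle
for $N \le 5$. Enumeration is refused above $N = 7$: the next order has
11117 classes and a $2^{28}$ labeled scan, out of proportion for a
desk-scale tool.

## Monte Carlo

`estimate_fixation()` runs the embedded chain directly: at each step one
frontier replacement $(i, j)$ is drawn with probability proportional to
$r w_{ij}$ (invasion) or $w_{ij}$ (recovery), with incremental $O(d_j)$
updates of the frontier weights after each flip. Conditioning on
state-changing events leaves absorption probabilities untouched — the
justification for simulating the embedded rather than the lazy chain — and
removes the self-loop-dominated waiting that makes naive simulation slow
near absorption.

* **Randomness.** The simulator consumes R's own RNG stream
  (`unif_rand`), so `set.seed()` gives bit-reproducible estimates; trials
  run sequentially in one stream, which keeps the contract simple
  (`identical` outputs for identical `(seed, trials, g, r)`). No per-trial
  substream scheme is needed at these trial counts.
* **Intervals.** Wilson score intervals at the 99% level, because fixation
  probabilities are routinely near 0 where the Wald interval undercovers.
* **$r = 0$** is allowed (deviation curves start there): the invader never
  reproduces and extinction is certain; the recovery rates stay positive,
  so the simulation terminates.

What the simulation emulates is exactly the model above — it is a second,
independent route to the same quantity, used in the tests to cross-check
the exact solvers within binomial error. What it cannot do is certify a
sign: near the baseline the deviation of an order-$N$ ell-graph shrinks as
$2/N$, so a $z$-test at any fixed trial count eventually loses power. The
suite therefore makes Monte Carlo assertions only in calibrated form
(estimates within 4 standard errors of exact values at $10^6$ trials; 99%
interval coverage at least 0.95 over 200 replicates), and all
suppressor/amplifier *verdicts* rest on exact arithmetic.

## Problem sizes and test design

The suite and the acceptance script run the study at desk scale, chosen to
finish in minutes while leaving every verdict exact: full-state solves up
to $K_{10}$ (1024 states), lumped-vs-full equality for orders 6 and 8 at
$r \in \{1/2, 1, 2, 5\}$, symbolic certification for orders 6, 8, 10,
the exhaustive exact scan at order 6 (112 classes × 40 grid points), and
$10^6$-trial Monte Carlo calibration. Test seeds are fixed arbitrary
constants; tolerance choices (4 standard errors, coverage ≥ 0.95) are
standard calibration bounds, not tuned values.

## Known limitations

* Birth–death updating only; death–birth dynamics can reverse
  amplifier/suppressor roles and is not implemented.
* Symmetry lumping is specific to the ell-family's known automorphisms;
  there is no general automorphism detection.
* The full-state solver is capped (default $N \le 14$) by the width of the
  middle levels; beyond that only the lumped family and simulation scale.
* Grid verdicts certify the grid, not the continuum; only the symbolic
  route proves a property for all $r > 1$.
* The suppressor deviation vanishes as $N$ grows (the two extra vertices
  carry weight $2/N$ of the uniform initialization), so distinguishing
  large ell-graphs from the baseline by simulation requires trial counts
  growing quadratically in the inverse deviation.
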