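---
title: "Discrete Morse filtrations for the persistent homology of unweighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete Morse filtrations for the persistent homology of unweighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morseph)
```

## The problem

Persistent homology tracks how topological features — connected components,
cycles, voids — appear and disappear as a space is built up through a nested
sequence of subcomplexes.  For a weighted network the edge weights induce
such a filtration naturally; an unweighted network offers no order in which
to add its simplices.  The baseline remedy is to filter the clique complex by
simplex dimension (vertices, then edges, then triangles, ...), but that
filtration has only `d + 1` steps and flattens most of the structure: it
barely distinguishes random-graph families with equal size and density.

`morseph` instead equips the clique complex of a simple graph with a
*discrete Morse function*: a real weight on every simplex such that each
simplex has at most one cofacet of lower-or-equal weight and at most one
facet of greater-or-equal weight.  Simplices violating neither bound in the
strict sense — every cofacet strictly heavier, every facet strictly lighter
— are *critical*, and all changes in homology happen at the weights of
critical simplices.  The filtration by level subcomplexes can therefore be
collapsed onto the subsequence of distinct critical weights without changing
a single persistence point, which both shortens the computation and spreads
the network's structure over a real-valued axis.

## The weight construction

Vertex weights come from the degree:

```
g(v) = deg_max - degree(v) + eps_v,   eps_v ~ Uniform(0, 0.5)
```

High-degree vertices get *low* weights and enter the filtration first; the
noise makes all vertex values pairwise distinct.  Both properties matter.
The inverse relation front-loads the structurally important vertices, and
distinctness lets the edge assignment pair an edge with its heavier
endpoint: if that endpoint has not been consumed by another pairing, the
edge copies its weight (neither is then critical); otherwise the edge gets
the endpoint weight plus fresh `Uniform(0, 0.5)` noise.  The same rule is
applied dimension by dimension up to the construction cap: each simplex
locates its heaviest facet, pairs with it if it is still free, and falls
back to facet weight plus noise if not.  The output provably satisfies the
discrete Morse condition, and `isDiscreteMorse()` re-verifies it directly
from the definitions on every complex the test suite generates.

Two consequences are worth knowing.  First, weights are weakly monotone
along faces, so a simplex's level-subcomplex entry value equals its own
weight; `entryValues()` still computes the general minimum-over-cofaces so
that injected, non-constructed weight vectors behave correctly.  Second,
pair weights are copied exactly, so equal weights are common by design and
zero-persistence pairs are dropped from every diagram.

### Processing order

Within a dimension the order in which simplices are processed is a free
parameter of the construction: any order yields a valid discrete Morse
function, but the greedy pairing is not order-neutral.  An order correlated
with the storage order of the complex (for example lexicographic by vertex
labels) walks through dense regions in runs of simplices that share facets,
and pairs almost everything; an uncorrelated order wastes more flags and
leaves noticeably more critical simplices in dense cores, which is what
implementations iterating over hash-ordered containers produce in practice.
The package draws a uniform random permutation per dimension from the same
seeded RNG stream.  This keeps the critical counts insensitive to how the
cliques happen to be enumerated, makes runs bit-reproducible for a fixed
seed, and reproduces the published optimality values for all five benchmark
model families, which an intentionally label-correlated order does not (it
overshoots the optimality indicator on the geometric models, where dense
cores dominate).

### Optimality

With `m_p` critical `p`-simplices, `n_p` simplices and Betti numbers
`beta_p`, the indicator

```
mu = (sum n_p - sum m_p) / (sum n_p - sum beta_p)
```

is 1 when the construction attains the theoretical minimum (`m_p = beta_p`
is a lower bound) and 0 when every simplex is critical, as for the
dimension function.  `mu` is reported by `runSummary()` and aggregated over
seeded replicates by `runMuExperiment()`.

## Filtration, persistence, diagram distances

`criticalFiltration()` assigns each simplex the smallest critical weight at
least as large as its entry value; simplices beyond the last critical
weight are assigned the last critical weight, which completes the complex
in the final step without adding or moving any nonzero-persistence point
(no critical weight lies beyond, so no homology change can either).  The
test suite checks exactly this equivalence: the diagram of the full-weight
filtration, snapped onto the critical subsequence with `snapDiagram()`,
must equal the critical-filtration diagram point for point.

Persistence is computed over GF(2) — orientation is immaterial there, which
suits clique complexes — by standard left-to-right boundary-matrix column
reduction, implemented in C++ with sparse columns and validated against a
dense Gaussian-elimination oracle, a rank-nullity Betti computation and a
component count.  Ties in filtration weight are ordered by dimension and
then lexicographically, so faces always precede cofaces.

Diagrams are normalized by `w_N = 1 + max f` (so all finite coordinates lie
in `[0, 1)`) and essential classes are drawn at a death of exactly 1.  The
dimension-function filtration normalizes by the complex dimension instead,
mapping its index range onto `[0, 1]`.  The persistence of a class is
reported as death minus birth throughout.

Bottleneck and q-Wasserstein distances between diagrams use the standard
diagonal augmentation (each side is extended by the projections of the
other side's points; unequal cardinalities are handled by construction) and
are exact: the bottleneck value is found by binary search over the finite
candidate set of pairwise and diagonal costs with a Hopcroft–Karp
feasibility test — a threshold is feasible precisely when the points too
persistent to fall to the diagonal can each be matched within the threshold,
checked on both sides — and the Wasserstein assignment is solved by an
O(n^3) Hungarian algorithm.  Both are cross-checked against exhaustive
enumeration over all augmented bijections on small diagrams.  Diagrams are
pooled across dimensions by default, matching the whole-complex diagram the
benchmark comparisons use; `perDimensionDistance()` reports per-dimension
values.

## The model-network generators

The benchmark conditions are five families at `n = 1000` vertices and
expected average degree 4, which are also the generator defaults exposed by
`defaultModelSpecs()`:

* **ER** `G(n, p)`, `p = 0.004`: every pair is an edge independently.
* **WS** `k = 4`, rewiring `p = 0.5`: ring lattice with each lattice edge's
  clockwise endpoint rewired with probability `p` to a uniform non-duplicate
  target, so the edge count is exactly `nk/2`.
* **BA** `m = 2`: preferential attachment from a seed of `m` isolated
  vertices; the first arrival connects to all of them (degree-0 bootstrap is
  uniform), so the edge count is exactly `m(n - m)` and the graph is
  connected.
* **Hyperbolic** (`gamma = 2`, `T = 0`): points on a hyperbolic disk of
  radius `R`, radial density proportional to `sinh(r/2)`, connected when
  their hyperbolic distance is at most `R`.  `R` is calibrated by bisection
  so the *expected* average degree is `k`; the expectation is evaluated by
  stratified quadrature on the radial inverse CDF rather than by Monte
  Carlo, because with `gamma = 2` the sampled mean degree is heavy-tailed
  enough that a few-sample Monte-Carlo estimate misplaces `R` badly.
  Realized mean degrees still fluctuate strongly across seeds — that is a
  property of the model, not of the calibration.
* **Spherical** (`gamma = Inf`, `T = 0`): in the `gamma -> Inf` limit the
  radial coordinates collapse to the disk boundary and the model
  degenerates to a geometric graph on the circle; points are uniform on the
  circle and connected within angular distance `theta_R = pi k/(n - 1)`.
  The circle — not a higher-dimensional sphere — is the right limit here:
  it reproduces the benchmark instance counts (about `n e^{-k/2}` of the
  vertices end up in separated arcs, clique complexes of circle graphs are
  unions of contractible pieces, hence the characteristic `beta_1 = 0`),
  while a 2-sphere variant at the same mean degree is measurably more
  ER-like (fewer components, nonzero `beta_1`) and does not match.

All generators emit simple graphs, are bit-reproducible for a fixed seed,
and are also reachable through plain text edge lists via `readEdgelist()`.

## What the tests do and do not show

The acceptance suite regenerates the study conditions from scratch: mean
`mu` over 10 seeded replicates per model against the published values (each
within three reported standard deviations), Betti numbers of an ER instance
against published instance values (within three sampling standard
deviations estimated from 20 replicates), the discrete-Morse property and
the Morse inequalities/Euler identity on every run, the
full-versus-critical filtration equivalence on 100 graphs, oracle
agreement of the reduction and the distances, and the qualitative ordering
of mean bottleneck distances (BA–ER and spherical–hyperbolic both exceed
ER–WS).  Problem sizes mirror the benchmark protocol (n = 1000, 10
replicates) for the headline quantities and use smaller seeded sweeps
(n up to 200) for the property checks.

These are model networks: passing says the pipeline reproduces the
published behaviour of the five synthetic families, not that any biological
claim about a particular protein-interaction network is re-established.
Real networks enter through `readEdgelist()` and run through the identical
pipeline, but their raw data are not shipped.

## Numerical choices and limitations

* The construction cap defaults to dimension 3 (cliques of up to four
  vertices), the benchmark setting.  Betti numbers and diagram points in
  the top dimension of a capped complex are truncation-affected — missing
  `(cap+1)`-simplices can never fill `cap`-dimensional holes — and should be
  read as properties of the capped complex.
* Exact weight ties in the facet-maximum search are broken toward the
  lexicographically smallest facet.  By construction all same-dimension
  weights are distinct with probability one, so this is a guard, not a
  code path that shapes results.
* The degenerate `mu` case (every simplex a homology generator, e.g. a
  single vertex) is defined as 1 with a warning.
* Noise draws: vertex noise in sorted-vertex order, the per-dimension
  processing permutation, then fallback noise in processing order — all
  from one seeded stream, so every result is reproducible from `(graph
  seed, Morse seed)`.
* The Wasserstein solver is cubic in the total point count and intended
  for desk-scale diagrams; the bottleneck solver handles the benchmark
  diagrams (thousands of points) comfortably.
* Optimal Morse matchings, critical-pair cancellation and gradient paths
  are out of scope; the construction is greedy and near-optimal in
  practice, not optimal (which is computationally hard in general).

## A worked example

```{r example}
g <- fixtureGraph("twoTriangles")   # 9 vertices, 11 edges, two triangles
s <- runSummary(g, seed = 7)
s
attr(s, "mu")
```

The two-triangle fixture reproduces, for every seed, the canonical story of
the reduced filtration: four critical simplices (two vertices, two edges),
a second component born at the second critical weight that merges at the
third, and the independent cycle appearing at the fourth.

```{r example2}
res <- analyzeNetwork(g, seed = 7)
diagramPoints(res$diagram)
criticalWeights(res$critical)
```
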