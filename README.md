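# morseph

Persistent homology of unweighted, undirected networks through discrete
Morse theory.

## The problem

Unweighted networks offer no natural order in which to add their simplices,
so the standard edge-weight filtrations of topological data analysis do not
apply, and the fallback of filtering the clique complex by simplex dimension
has too few steps to distinguish networks of equal size and density.
`morseph` builds a *discrete Morse function* on the clique complex of a
simple graph: vertex weights

    g(v) = deg_max − degree(v) + ε,    ε ~ Uniform(0, 0.5),

so important (high-degree) vertices enter the filtration first, and weights
for edges, triangles and tetrahedra chosen greedily so that every simplex
has at most one cofacet of lower-or-equal weight (the set `U`) and at most
one facet of greater-or-equal weight (the set `V`).  Simplices with both
sets empty are *critical*; all births and deaths of homology classes happen
at critical weights, so the filtration collapses from one step per distinct
weight to one step per critical weight — typically a > 90% reduction,
quantified by the optimality indicator

    μ = (Σ n_p − Σ m_p) / (Σ n_p − Σ β_p)  ∈ [0, 1],

where `n_p`, `m_p`, `β_p` are the simplex counts, critical counts and
Betti numbers (μ = 1 is the theoretical optimum `m_p = β_p`; μ = 0 means
every simplex is critical, as for the dimension function).  Persistence is
computed over GF(2) by boundary-matrix reduction, and persistence diagrams
are compared with exact bottleneck and q-Wasserstein distances, which
separate random-graph families (Erdős–Rényi, Watts–Strogatz,
Barabási–Albert, hyperbolic and spherical geometric graphs) that plain
Betti numbers cannot.

The package is aimed at network scientists who want higher-order (beyond
pairwise) structure out of unweighted graphs — protein-interaction
networks, infrastructure grids, communication and social networks — and at
anyone needing a seeded, reproducible network-TDA pipeline in R.

## A worked example

```r
library(morseph)

g <- fixtureGraph("twoTriangles")  # 9 vertices, 11 edges, 2 triangles
s <- runSummary(g, seed = 7)
s
#>   p  n  m beta
#> 1 0  9  2    1
#> 2 1 11  2    1
#> 3 2  2  0    0
#> 4 3  0  0    0
attr(s, "mu")
#> [1] 0.9
```

Of the 22 simplices only four are critical (two vertices, two edges),
giving μ = (22 − 4)/(22 − 2) = 0.9.  The reduced filtration has four
steps; its persistence diagram

```r
res <- analyzeNetwork(g, seed = 7)
diagramPoints(res$diagram)
#>   dim     birth    death multiplicity
#> 1   0 0.4860313      Inf            1
#> 2   0 2.0578489 3.693242            1
#> 3   1 3.8490159      Inf            1
```

reads: one component persists forever (born at the first critical weight,
the degree-5 hub vertex), a second component is born at the second critical
weight and merges at the third (a critical edge), and the network's single
independent cycle appears at the fourth critical weight and never dies.
On model networks the same pipeline runs at n = 1000 in about a second:

```r
mu <- runMuExperiment(defaultModelSpecs(), replicates = 10, seed = 1)
mu
#>   model   mean_mu       sd_mu replicates
#> 1    er 0.9295542 0.005811823         10
#> 2    ws 0.8912203 0.005444778         10
#> 3    ba 0.9889018 0.004042978         10
#> 4   sph 0.9400477 0.003509718         10
#> 5   hyp 0.9529251 0.008628051         10
```

i.e. the construction stays within a few percent of the optimal number of
critical simplices on all five benchmark families.

Graphs come in as plain-text edge lists (`readEdgelist()`), from the seeded
generators (`sampleER()`, `sampleWS()`, `sampleBA()`, `sampleHGG()`), or as
named igraph objects.  Diagrams export to TSV (`writeDiagram()`,
`barcode()`), and `inst/scripts/morseph.R` provides a command-line front
end (`generate`, `summary`, `morse`, `filter`, `persist`, `distance`,
`compare-models`, `mu-experiment`).

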