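Package: morseph
Title: Discrete Morse Filtrations and Persistent Homology of Unweighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes persistent homology of unweighted, undirected networks
    through a discrete Morse function built on the clique complex. Vertex
    weights are derived from vertex degrees plus small uniform noise, weights
    of higher simplices are assigned so that the resulting function satisfies
    the discrete Morse condition, and the filtration is reduced to the
    subsequence of critical weights without changing the persistence diagram.
    Includes seeded generators for Erdos-Renyi, Watts-Strogatz,
    Barabasi-Albert and hyperbolic/spherical random geometric graphs, GF(2)
    boundary-matrix reduction, barcode and diagram export, exact bottleneck
    and q-Wasserstein distances between persistence diagrams, and benchmark
    experiments comparing model networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
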