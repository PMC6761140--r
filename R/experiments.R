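#' Model-network specification
#'
#' @param model one of "er", "ws", "ba", "hgg".
#' @param n vertex count.
#' @param p edge probability (er) or rewiring probability (ws).
#' @param k neighbourhood size (ws) or target average degree (hgg).
#' @param m edges per arriving vertex (ba).
#' @param gamma tail exponent (hgg); Inf selects the spherical variant.
#' @param temp temperature (hgg); only 0 is supported.
#' @return a list of class "modelSpec".
#' @export
modelSpec <- function(model = c("er", "ws", "ba", "hgg"), n, p = NULL,
                      k = NULL, m = NULL, gamma = NULL, temp = NULL) {
  model <- match.arg(model)
  pars <- Filter(Negate(is.null),
                 list(p = p, k = k, m = m, gamma = gamma, temp = temp))
  structure(c(list(model = model, n = n), pars), class = "modelSpec")
}

#' Generate a graph from a model specification
#'
#' @param spec a [modelSpec()].
#' @param seed optional integer seed.
#' @return a named igraph object.
#' @export
generateModel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "modelSpec"))
  switch(spec$model,
    er  = sampleER(spec$n, spec$p, seed = seed),
    ws  = sampleWS(spec$n, spec$k, spec$p, seed = seed),
    ba  = sampleBA(spec$n, spec$m, seed = seed),
    hgg = sampleHGG(spec$n, spec$k, gamma = spec$gamma %||% 2,
                    temp = spec$temp %||% 0, seed = seed))
}

#' The five benchmark model settings
#'
#' ER(1000, p = 0.004), WS(1000, k = 4, p = 0.5), BA(1000, m = 2), the
#' spherical random geometric graph (n = 1000, k = 4, gamma = Inf, T = 0)
#' and the hyperbolic one (n = 1000, k = 4, gamma = 2, T = 0) — five
#' models of equal size and expected average degree about 4.
#'
#' @param n vertex count (default 1000).
#' @return named list of [modelSpec()] objects.
#' @export
defaultModelSpecs <- function(n = 1000) {
  list(
    er  = modelSpec("er", n, p = if (n == 1000) 0.004 else 4 / (n - 1)),
    ws  = modelSpec("ws", n, k = 4, p = 0.5),
    ba  = modelSpec("ba", n, m = 2),
    sph = modelSpec("hgg", n, k = 4, gamma = Inf),
    hyp = modelSpec("hgg", n, k = 4, gamma = 2))
}

#' Full discrete-Morse persistence analysis of one network
#'
#' Convenience driver: builds the clique complex up to `cap`, constructs
#' the degree-based discrete Morse function, extracts critical simplices,
#' builds the requested filtration and computes its persistence diagram,
#' Betti numbers and the optimality indicator mu.
#'
#' @param graph a named igraph object (see [readEdgelist()] or the
#'   generators).
#' @param cap clique-complex dimension cap (default 3).
#' @param seed integer seed for the Morse noise; required for reproducible
#'   output.
#' @param scheme filtration scheme, one of "critical", "full", "dimension".
#' @return a list with elements `complex`, `morse`, `critical`,
#'   `filtration`, `diagram`, `np`, `mp`, `beta`, `mu`, `nSteps`.
#' @examples
#' res <- analyzeNetwork(fixtureGraph("P3"), seed = 7)
#' res$mu   # 1: the path achieves the theoretical minimum
#' @export
analyzeNetwork <- function(graph, cap = 3, seed = NULL,
                           scheme = c("critical", "full", "dimension")) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  cc <- buildCliqueComplex(graph, cap = cap)
  d <- complexDim(cc)
  if (scheme == "dimension") {
    flt <- dimensionFiltration(cc)
    dg <- persistenceDiagram(flt, cc)
    np <- as.integer(simplexCounts(cc))
    beta <- as.integer(bettiNumbers(dg))
    return(list(complex = cc, morse = NULL, critical = NULL, filtration = flt,
                diagram = dg, np = np, mp = np, beta = beta,
                mu = if (sum(np) > sum(beta)) 0 else 1,
                nSteps = length(unique(flt@weights))))
  }
  g <- vertexFunction(graph)
  mf <- assignMorseFunction(cc, g)
  crit <- findCritical(cc, mf)
  flt <- if (scheme == "critical") criticalFiltration(cc, mf, crit)
         else fullFiltration(cc, mf)
  dg <- persistenceDiagram(flt, cc)
  np <- as.integer(simplexCounts(cc))
  mp <- as.integer(criticalCounts(crit))
  beta <- as.integer(bettiNumbers(dg))
  list(complex = cc, morse = mf, critical = crit, filtration = flt,
       diagram = dg, np = np, mp = mp, beta = beta,
       mu = optimalityMu(np, mp, beta),
       nSteps = length(unique(flt@weights)))
}

#' Per-dimension summary table of one network
#'
#' One row per dimension 0..cap with the simplex count n_p, the critical
#' count m_p and the Betti number beta_p, plus the optimality indicator mu
#' and the number of filtration steps as attributes.  Identical across
#' repeated runs with the same seed.
#'
#' @param input an igraph object or a path to an edge list.
#' @inheritParams analyzeNetwork
#' @return data.frame with columns p, n, m, beta; attributes `mu`,
#'   `nSteps`, `seed`.
#' @export
runSummary <- function(input, cap = 3, seed = NULL,
                       scheme = c("critical", "full", "dimension")) {
  graph <- if (is.character(input)) readEdgelist(input) else input
  res <- analyzeNetwork(graph, cap = cap, seed = seed, scheme = match.arg(scheme))
  pad <- function(v) c(v, rep(0L, cap + 1L - length(v)))
  out <- data.frame(p = 0:cap, n = pad(res$np), m = pad(res$mp),
                    beta = pad(res$beta))
  attr(out, "mu") <- res$mu
  attr(out, "nSteps") <- res$nSteps
  attr(out, "seed") <- seed
  out
}

#' Optimality-indicator experiment over model networks
#'
#' For each model specification, generates `replicates` seeded graphs, runs
#' the full pipeline on each and aggregates the optimality indicator mu
#' (mean and standard deviation across replicates), mirroring the benchmark
#' protocol for model networks.
#'
#' @inheritParams modelDistanceMatrix
#' @return data.frame with columns model, mean_mu, sd_mu, replicates; the
#'   per-replicate results (np, mp, beta, mu, diagram) are kept in
#'   attribute `"replicates"` as a named list of lists.
#' @export
runMuExperiment <- function(specs = defaultModelSpecs(), replicates = 10,
                            seed = 1, cap = 3) {
  if (replicates < 2) stop("replicates must be >= 2")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * length(specs) * replicates),
                  ncol = 2L)
  detail <- vector("list", length(specs))
  names(detail) <- names(specs)
  row <- 0L
  for (m in names(specs)) {
    detail[[m]] <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      row <- row + 1L
      g <- generateModel(specs[[m]], seed = seeds[row, 1L])
      res <- analyzeNetwork(g, cap = cap, seed = seeds[row, 2L])
      detail[[m]][[r]] <- res[c("np", "mp", "beta", "mu", "diagram")]
    }
  }
  out <- data.frame(
    model = names(specs),
    mean_mu = vapply(detail, function(d) mean(vapply(d, `[[`, numeric(1), "mu")), numeric(1)),
    sd_mu = vapply(detail, function(d) stats::sd(vapply(d, `[[`, numeric(1), "mu")), numeric(1)),
    replicates = replicates, row.names = NULL)
  attr(out, "replicates") <- detail
  out
}
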