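#' Seeded Erdos-Renyi random graph G(n, p)
#'
#' Every one of the choose(n, 2) vertex pairs is an edge independently with
#' probability p, so the expected average degree is p(n-1).
#'
#' @param n number of vertices (>= 1).
#' @param p edge probability in [0, 1].
#' @param seed optional integer seed; for a fixed seed the graph is
#'   bit-reproducible.
#' @return a named igraph object with vertices `v0001`, `v0002`, ...
#' @export
sampleER <- function(n, p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- vLabels(n)
  sortGraphVertices(g)
}

#' Seeded Watts-Strogatz small-world graph
#'
#' Starts from the ring lattice in which every vertex is joined to its k
#' nearest neighbours (k/2 on each side).  Each lattice edge, with
#' probability p, has its clockwise endpoint detached and reattached to a
#' vertex drawn uniformly among those creating neither a self-loop nor a
#' duplicate edge, so the edge count is exactly nk/2.
#'
#' @param n number of vertices.
#' @param k even neighbourhood size, 0 < k < n.
#' @param p rewiring probability.
#' @inheritParams sampleER
#' @return a named igraph object.
#' @export
sampleWS <- function(n, k, p, seed = NULL) {
  if (k %% 2 != 0) stop("k must be even")
  if (k <= 0 || k >= n) stop("k must satisfy 0 < k < n")
  if (p < 0 || p > 1) stop("p must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n); k <- as.integer(k)
  adj <- lapply(seq_len(n), function(i)
    sort(unique(vapply(c(seq_len(k %/% 2L), -seq_len(k %/% 2L)),
                       function(j) as.integer((i - 1L + j) %% n) + 1L, integer(1)))))
  # rewire ring edges (i, i+j) in the standard sweep order: ring offset outer,
  # origin vertex inner
  for (j in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      old <- ((i - 1L + j) %% n) + 1L
      if (!(old %in% adj[[i]])) next        # already rewired away by symmetry? (cannot happen)
      if (stats::runif(1) >= p) next
      allowed <- setdiff(seq_len(n), c(i, adj[[i]]))
      if (!length(allowed)) next
      w <- allowed[sample.int(length(allowed), 1L)]
      adj[[i]] <- sort(c(setdiff(adj[[i]], old), w))
      adj[[old]] <- setdiff(adj[[old]], i)
      adj[[w]] <- sort(c(adj[[w]], i))
    }
  }
  el <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- adj[[i]][adj[[i]] > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  graphFromIntEdges(el, n)
}

#' Seeded Barabasi-Albert preferential-attachment graph
#'
#' The seed graph consists of m isolated vertices; each arriving vertex
#' attaches to m distinct existing vertices sampled proportionally to their
#' current degree (uniformly while all degrees are zero, so the first
#' arrival connects to all seed vertices).  The edge count is therefore
#' exactly m(n - m) and the graph is connected.
#'
#' @param n number of vertices.
#' @param m edges added per arriving vertex, 1 <= m < n.
#' @inheritParams sampleER
#' @return a named igraph object.
#' @export
sampleBA <- function(n, m, seed = NULL) {
  if (m < 1 || m >= n) stop("m must satisfy 1 <= m < n")
  if (!is.null(seed)) set.seed(seed)
  deg <- integer(n)
  from <- integer((n - m) * m)
  to <- integer((n - m) * m)
  pos <- 0L
  for (v in seq.int(m + 1L, n)) {
    prev <- seq_len(v - 1L)
    w <- deg[prev]
    tgt <- if (sum(w) == 0) sample(prev, m) else sample(prev, m, prob = w)
    idx <- pos + seq_len(m)
    from[idx] <- v; to[idx] <- tgt
    pos <- pos + m
    deg[v] <- deg[v] + m
    deg[tgt] <- deg[tgt] + 1L
  }
  graphFromIntEdges(cbind(from, to), n)
}

#' Seeded hyperbolic / spherical random geometric graph (T = 0)
#'
#' For finite gamma, n points are placed on a hyperbolic disk of radius R
#' (uniform angle; radial density proportional to sinh(alpha r) with
#' alpha = (gamma - 1)/2, curvature zeta = 1) and two points are joined
#' when their hyperbolic distance is at most R.  R is calibrated by
#' bisection so that the expected average degree equals k (quadrature over
#' the radial distribution; see [calibrateHypRadius]).  For gamma = Inf the
#' spherical variant is used: in the gamma -> Inf limit all radial
#' coordinates collapse to the disk boundary and the model degenerates to a
#' geometric graph on the circle, so n points are placed uniformly on the
#' circle and joined when their angular distance is at most
#' theta_R = pi k / (n - 1), making the expected average degree exactly k.
#'
#' @param n number of vertices.
#' @param k target expected average degree (> 0).
#' @param gamma tail exponent in [2, Inf]; Inf selects the spherical model.
#' @param temp temperature; only the step-function limit temp = 0 is
#'   supported.
#' @inheritParams sampleER
#' @return a named igraph object.
#' @export
sampleHGG <- function(n, k, gamma = 2, temp = 0, seed = NULL) {
  if (temp != 0) stop("unsupported parameter: only temperature 0 is implemented")
  if (k <= 0) stop("k must be > 0")
  if (gamma < 2) stop("gamma must be in [2, Inf]")
  if (!is.null(seed)) set.seed(seed)
  if (is.infinite(gamma)) {
    thr <- pi * k / (n - 1)
    if (thr > pi) stop("calibration error: k too large for n on the circle")
    theta <- stats::runif(n, 0, 2 * pi)
    dtheta <- abs(outer(theta, theta, "-"))
    A <- pmin(dtheta, 2 * pi - dtheta) <= thr
  } else {
    alpha <- (gamma - 1) / 2
    R <- calibrateHypRadius(n, k, alpha)
    theta <- stats::runif(n, 0, 2 * pi)
    u <- stats::runif(n)
    r <- acosh(1 + u * (cosh(alpha * R) - 1)) / alpha
    ch <- cosh(r); sh <- sinh(r)
    cosd <- cos(theta) %o% cos(theta) + sin(theta) %o% sin(theta)
    A <- (ch %o% ch) - (sh %o% sh) * cosd <= cosh(R)  # hyperbolic distance <= R
  }
  diag(A) <- FALSE
  el <- which(A & upper.tri(A), arr.ind = TRUE)
  graphFromIntEdges(el, n)
}

# Disk radius R such that the expected average degree of the T=0 model is k.
# The connection probability of two points at radii r1, r2 is theta*/pi with
# cos(theta*) = (cosh r1 cosh r2 - cosh R)/(sinh r1 sinh r2); the expectation
# over radii is evaluated by stratified quadrature on the inverse CDF of the
# radial density (proportional to sinh(alpha r) on [0, R]), and R is found
# by bisection.  Deterministic, so calibration consumes no RNG draws.
calibrateHypRadius <- function(n, k, alpha, gridSize = 400L, tol = 1e-3) {
  expDeg <- function(R) {
    q <- (seq_len(gridSize) - 0.5) / gridSize
    r <- acosh(1 + q * (cosh(alpha * R) - 1)) / alpha
    ch <- cosh(r); sh <- sinh(r)
    carg <- ((ch %o% ch) - cosh(R)) / (sh %o% sh)
    (n - 1) * mean(acos(pmin(1, pmax(-1, carg)))) / pi
  }
  lo <- 0.5; hi <- 2
  while (expDeg(hi) > k) { lo <- hi; hi <- hi * 2; if (hi > 500) stop("calibration error: k too small") }
  if (expDeg(lo) < k) stop("calibration error: k too large for n")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    d <- expDeg(mid)
    if (abs(d - k) <= tol * k) return(mid)
    if (d > k) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

vLabels <- function(n) sprintf("v%0*d", max(4L, nchar(n)), seq_len(n))

graphFromIntEdges <- function(el, n) {
  lab <- vLabels(n)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- lab
  if (!is.null(el) && nrow(el))
    g <- igraph::add_edges(g, t(cbind(lab[el[, 1L]], lab[el[, 2L]])))
  g <- igraph::simplify(g)
  sortGraphVertices(g)
}

#' Deterministic toy graphs for examples and tests
#'
#' @param name one of `"K1"` (single vertex), `"K2"` (one edge), `"P3"`
#'   (path a-b-c), `"K3"` (triangle), `"C4"` (4-cycle) or
#'   `"twoTriangles"` (a 9-vertex, 11-edge graph with two triangles, one
#'   pendant vertex, one degree-5 hub and a single independent cycle).
#' @return a named igraph object.
#' @export
fixtureGraph <- function(name) {
  edges <- switch(name,
    K1 = character(0),
    K2 = c("a", "b"),
    P3 = c("a", "b", "b", "c"),
    K3 = c("a", "b", "a", "c", "b", "c"),
    C4 = c("a", "b", "b", "c", "c", "d", "a", "d"),
    twoTriangles = c("v7", "v8", "v1", "v7", "v5", "v7", "v6", "v7", "v0", "v7",
                     "v1", "v2", "v2", "v3", "v3", "v4", "v2", "v4", "v4", "v5",
                     "v0", "v6"),
    stop("unknown fixture graph: ", name))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  if (name == "K1") {
    g <- igraph::add_vertices(g, 1, name = "a")
  } else {
    vs <- sort(unique(edges), method = "radix")
    g <- igraph::add_vertices(g, length(vs), name = vs)
    g <- igraph::add_edges(g, edges)
  }
  sortGraphVertices(igraph::simplify(g))
}
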