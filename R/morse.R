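#' Degree-based vertex weights
#'
#' Assigns g(v) = deg_max - degree(v) + eps_v with eps_v drawn independently
#' and uniformly from (0, 0.5).  High-degree (important) vertices thus
#' receive low weights and enter the filtration early, and the noise makes
#' all values pairwise distinct, which lets the Morse construction pair as
#' many simplices as possible.  Noise is drawn in sorted-vertex order so a
#' fixed seed gives bit-identical values.
#'
#' @param graph an igraph object with vertex names.
#' @param seed optional integer seed.
#' @return named numeric vector of vertex weights, in sorted-label order.
#' @export
vertexFunction <- function(graph, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vl <- vertexLabels(graph)
  if (!length(vl)) return(setNames(numeric(0), character(0)))
  deg <- igraph::degree(graph)[vl]
  dm <- max(deg, 0)
  g <- dm - deg + stats::runif(length(vl), 0, 0.5)
  while (anyDuplicated(g)) {   # measure-zero, but exact ties are fatal downstream
    i <- which(duplicated(g))
    g[i] <- dm - deg[i] + stats::runif(length(i), 0, 0.5)
  }
  setNames(as.numeric(g), vl)
}

#' Construct a discrete Morse function on a clique complex
#'
#' Given distinct vertex weights g, processes the simplices dimension by
#' dimension, within a dimension in a seeded-random order (a uniform
#' permutation drawn from the same RNG stream, so a fixed seed gives
#' bit-identical output).  For each simplex the facet with the largest
#' weight is located (exact ties, which have probability zero, are broken
#' toward the lexicographically smallest facet).  If that facet has not
#' yet been consumed by another pairing, the simplex copies its weight and
#' the two are paired (neither is critical); otherwise the simplex gets
#' the facet weight plus fresh uniform noise from (0, 0.5).  The result
#' satisfies the discrete Morse condition on every complex: each simplex
#' has at most one coface of lower-or-equal weight and at most one face of
#' greater-or-equal weight.
#'
#' The processing order within a dimension is a free choice of the
#' construction; the greedy pairing is near-optimal under any order, but
#' an order correlated with the storage order of the complex pairs
#' systematically better inside dense cores than an uncorrelated one.  A
#' random order makes the critical counts insensitive to how the cliques
#' happen to be enumerated.
#'
#' @param complex a [CliqueComplex-class] object.
#' @param g named numeric vector of distinct vertex weights covering all
#'   vertices of the complex (see [vertexFunction()]).
#' @param seed optional integer seed for the fallback noise (drawn in
#'   processing order).
#' @return a [MorseFunction-class] object.
#' @export
assignMorseFunction <- function(complex, g, seed = NULL) {
  stopifnot(is(complex, "CliqueComplex"))
  if (!is.null(seed)) set.seed(seed)
  np <- complex@np
  N <- sum(np)
  if (N == 0L)
    return(new("MorseFunction", values = numeric(0), pairedFace = integer(0),
               flagged = logical(0), seed = as.integer(seed %||% integer(0))))
  vkeys <- complex@keys[[1L]]
  if (!all(vkeys %in% names(g))) stop("g must be defined on every vertex of the complex")
  gv <- as.numeric(g[vkeys])
  if (anyDuplicated(gv)) stop("vertex weights must be pairwise distinct")
  f <- numeric(N)
  paired <- rep(NA_integer_, N)
  flag <- logical(N)
  f[seq_len(np[1L])] <- gv
  d <- length(np) - 1L
  for (s in seq_len(d + 1L)[-1L]) {
    Fm <- complex@facetIdx[[s]]
    off <- complex@offsets[s]
    for (i in sample.int(np[s])) {
      fac <- Fm[i, ]
      fv <- f[fac]
      mx <- max(fv)
      gm <- min(fac[fv == mx])          # lexicographically smallest on an exact tie
      gid <- off + i
      if (!flag[gm]) {
        f[gid] <- mx
        paired[gid] <- gm
        flag[gm] <- TRUE
      } else {
        f[gid] <- mx + stats::runif(1L, 0, 0.5)
      }
    }
  }
  new("MorseFunction", values = f, pairedFace = paired, flagged = flag,
      seed = as.integer(seed %||% integer(0)))
}

#' Morse weights of a function
#' @param x a [MorseFunction-class] object or a bare numeric vector.
#' @return numeric vector of per-simplex weights in global-id order.
#' @export
morseValues <- function(x) {
  if (is(x, "MorseFunction")) x@values else as.numeric(x)
}

#' Paired maximal faces of a Morse function
#' @param x a [MorseFunction-class] object.
#' @return integer vector; for each simplex, the global id of its paired
#'   maximal face or NA.
#' @export
pairedFaces <- function(x) {
  stopifnot(is(x, "MorseFunction"))
  x@pairedFace
}

# per-simplex |U| and |V| counts for an arbitrary weight vector: the pair
# (face gamma, coface alpha) contributes to U_gamma and to V_alpha exactly
# when f(alpha) <= f(gamma)
morseSetSizes <- function(complex, f) {
  N <- nSimplices(complex)
  inc <- incidencePairs(complex)
  sel <- f[inc$coface] <= f[inc$face]
  list(U = tabulate(inc$face[sel], nbins = N),
       V = tabulate(inc$coface[sel], nbins = N))
}

#' Check the discrete Morse condition
#'
#' Verifies that every simplex has at most one cofacet with
#' lower-or-equal weight (|U| <= 1) and at most one facet with
#' greater-or-equal weight (|V| <= 1).  The dimension function is the
#' classical example that passes; a constant function fails on any complex
#' with an edge.
#'
#' @param complex a [CliqueComplex-class] object.
#' @param f a [MorseFunction-class] object or numeric vector of weights
#'   covering every simplex.
#' @return TRUE or FALSE; when FALSE, the attribute `"violations"` is a
#'   data.frame naming each offending simplex, the violated set and its size.
#' @export
isDiscreteMorse <- function(complex, f) {
  stopifnot(is(complex, "CliqueComplex"))
  f <- morseValues(f)
  if (length(f) != nSimplices(complex))
    stop("f must assign a weight to every simplex of the complex")
  uv <- morseSetSizes(complex, f)
  bad <- which(uv$U > 1L | uv$V > 1L)
  if (!length(bad)) return(TRUE)
  keys <- simplexKeys(complex)
  viol <- data.frame(
    simplex = rep(keys[bad], 2L),
    set = rep(c("U", "V"), each = length(bad)),
    size = c(uv$U[bad], uv$V[bad]))
  viol <- viol[viol$size > 1L, , drop = FALSE]
  structure(FALSE, violations = viol)
}

#' Critical simplices and critical weights
#'
#' A simplex is critical when both its U and V sets are empty: every
#' cofacet has strictly larger weight and every facet strictly smaller
#' weight.  The critical weights are the sorted distinct weights of the
#' critical simplices; they index the reduced filtration.
#'
#' @param complex a [CliqueComplex-class] object.
#' @param f a [MorseFunction-class] object (or weight vector) satisfying
#'   the discrete Morse condition.
#' @return a [CriticalSet-class] object.
#' @export
findCritical <- function(complex, f) {
  stopifnot(is(complex, "CliqueComplex"))
  fv <- morseValues(f)
  uv <- morseSetSizes(complex, fv)
  crit <- uv$U == 0L & uv$V == 0L
  dims <- simplexDims(complex)
  d <- complexDim(complex)
  mp <- vapply(0:max(d, 0L), function(p) sum(crit[dims == p]), integer(1))
  if (d < 0L) mp <- integer(0)
  new("CriticalSet", isCritical = crit, mp = mp,
      weights = sort(unique(fv[crit])))
}

#' Critical simplex counts per dimension
#' @param x a [CriticalSet-class] object.
#' @return named integer vector m_p.
#' @export
criticalCounts <- function(x) {
  stopifnot(is(x, "CriticalSet"))
  if (!length(x@mp)) return(setNames(integer(0), character(0)))
  setNames(x@mp, paste0("p", seq_along(x@mp) - 1L))
}

#' Critical weights
#' @param x a [CriticalSet-class] object.
#' @return strictly increasing numeric vector of distinct critical weights.
#' @export
criticalWeights <- function(x) {
  stopifnot(is(x, "CriticalSet"))
  x@weights
}

#' Optimality indicator of a discrete Morse function
#'
#' mu = (sum n_p - sum m_p) / (sum n_p - sum beta_p), where n_p are simplex
#' counts, m_p critical counts and beta_p Betti numbers.  mu = 1 means the
#' function attains the theoretical minimum number of critical simplices
#' (m_p cannot fall below beta_p), mu = 0 means every simplex is critical,
#' as for the dimension function.
#'
#' @param np,mp,betap integer vectors over dimensions 0..d (shorter vectors
#'   are zero-padded).
#' @return mu in [0, 1].  In the degenerate case sum n_p == sum beta_p
#'   (every simplex a homology generator, e.g. a single vertex) mu is 1 by
#'   convention, with a warning.
#' @export
optimalityMu <- function(np, mp, betap) {
  d <- max(length(np), length(mp), length(betap))
  pad <- function(v) c(v, rep(0L, d - length(v)))
  np <- pad(np); mp <- pad(mp); betap <- pad(betap)
  den <- sum(np) - sum(betap)
  if (den < 0) stop("sum of Betti numbers exceeds simplex count")
  if (den == 0) {
    warning("degenerate complex: every simplex is a homology generator; mu defined as 1")
    return(1)
  }
  (sum(np) - sum(mp)) / den
}
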